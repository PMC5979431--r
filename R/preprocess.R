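# internal: sample ids of a (tissue[, cohort]) group, in sheet order
samples_for <- function(samples, tissue, cohort = NULL) {
  keep <- samples$tissue == tissue
  if (!is.null(cohort)) keep <- keep & samples$cohort == cohort
  samples$sample_id[keep]
}

#' Filter to genes expressed in every sample of a tissue
#'
#' The analysis universe for a tissue is the set of genes whose RPKM is
#' strictly greater than `min_rpkm` in every sample of that tissue, all
#' cohorts jointly. The returned matrix is restricted to that tissue's
#' columns; gene order is preserved.
#'
#' @param matrix RPKM matrix, genes x samples.
#' @param samples Sample-sheet data.frame.
#' @param tissue Tissue whose samples define the filter.
#' @param min_rpkm Strict lower bound (default 1.0).
#' @return The filtered matrix (tissue samples only).
#' @export
filter_expressed <- function(matrix, samples, tissue, min_rpkm = 1.0) {
  ids <- samples_for(samples, tissue)
  if (length(ids) == 0L) stop("no samples for tissue '", tissue, "'")
  missing <- setdiff(ids, colnames(matrix))
  if (length(missing) > 0L) {
    stop("sample(s) absent from matrix: ", paste(missing, collapse = ", "))
  }
  sub <- matrix[, ids, drop = FALSE]
  keep <- rowSums(sub > min_rpkm) == ncol(sub)
  sub[keep, , drop = FALSE]
}

#' Cellwise log2 transformation
#'
#' @param matrix RPKM matrix.
#' @param pseudocount Added to every cell before the log; with the default 0
#'   the caller must have filtered to strictly positive values.
#' @return log2(matrix + pseudocount).
#' @export
log2_matrix <- function(matrix, pseudocount = 0) {
  shifted <- matrix + pseudocount
  if (any(shifted <= 0)) {
    bad <- which(shifted <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("nonpositive value at gene '%s', sample '%s' cannot be log-transformed",
                 rownames(matrix)[bad[1L]], colnames(matrix)[bad[2L]]))
  }
  log2(shifted)
}

#' Row-wise z-scaling
#'
#' Centers and scales each gene to mean 0, SD 1 (sample SD, n-1), the scale
#' used for heatmap display. Constant rows cannot be scaled and are emitted
#' as all zeros with a warning.
#'
#' @param matrix Numeric matrix with >= 2 columns.
#' @return Matrix of the same shape, rows scaled.
#' @export
row_zscore <- function(matrix) {
  stopifnot(ncol(matrix) >= 2L)
  mu <- rowMeans(matrix)
  sdv <- apply(matrix, 1L, stats::sd)
  flat <- sdv == 0
  if (any(flat)) {
    warning(sum(flat), " constant row(s) emitted as zeros: ",
            paste(utils::head(rownames(matrix)[flat], 5L), collapse = ", "))
    sdv[flat] <- 1
  }
  out <- (matrix - mu) / sdv
  out[flat, ] <- 0
  out
}
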