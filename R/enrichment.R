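#' Hypergeometric over-representation analysis
#'
#' One-sided (upper tail) hypergeometric test per gene set: given a
#' selection of k genes drawn from a universe of N, the p-value for a set
#' with m members in the universe and x members in the selection is
#' P(X >= x) with X ~ Hypergeometric(m, N - m, k). Sets are intersected
#' with the universe before testing; sets with no universe overlap are
#' skipped with a warning. Benjamini-Hochberg adjustment is applied across
#' the tested sets.
#'
#' @param selection Character vector of selected gene ids (must be a subset
#'   of `universe`).
#' @param universe Character vector of gene ids defining the background.
#' @param sets Named list of character vectors (e.g. [read_gene_sets()]).
#' @return Data.frame: set_name, set_size (in universe), overlap,
#'   universe_size, selection_size, p, adjusted_p; ordered by p.
#' @export
ora_hypergeometric <- function(selection, universe, sets) {
  universe <- unique(universe)
  selection <- unique(selection)
  if (length(selection) == 0L || length(universe) == 0L) {
    stop("selection and universe must be nonempty")
  }
  stray <- setdiff(selection, universe)
  if (length(stray) > 0L) {
    stop("selection gene(s) outside universe: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  }
  n_univ <- length(universe)
  n_sel <- length(selection)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    if (length(members) == 0L) {
      warning("gene set '", nm, "' has no overlap with the universe; skipped")
      return(NULL)
    }
    x <- length(intersect(members, selection))
    m <- length(members)
    p <- stats::phyper(x - 1L, m, n_univ - m, n_sel, lower.tail = FALSE)
    data.frame(set_name = nm, set_size = m, overlap = x,
               universe_size = n_univ, selection_size = n_sel,
               p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    return(data.frame(set_name = character(), set_size = integer(),
                      overlap = integer(), universe_size = integer(),
                      selection_size = integer(), p = numeric(),
                      adjusted_p = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$set_name), , drop = FALSE]
}

#' PCA quality control of samples
#'
#' Projects samples onto the leading principal components of the
#' gene-centered matrix (each gene centered across samples; no gene
#' scaling), the standard QC view in which replicates should cluster and
#' cohorts separate. By default the matrix is log2-transformed first; raw
#' RPKM can be requested.
#'
#' @param matrix Filtered RPKM matrix (genes x samples).
#' @param n_components Number of components to report (default 2).
#' @param log2_transform Transform to log2 before the decomposition
#'   (default TRUE).
#' @param pseudocount Passed to [log2_matrix()] when transforming.
#' @return List with `coordinates` (data.frame: sample_id, PC1, PC2, ...)
#'   and `variance_explained` (fractions in [0, 1], non-increasing).
#' @export
pca_qc <- function(matrix, n_components = 2L, log2_transform = TRUE,
                   pseudocount = 0) {
  if (ncol(matrix) < n_components) {
    stop("fewer samples (", ncol(matrix), ") than requested components (",
         n_components, ")")
  }
  x <- if (log2_transform) log2_matrix(matrix, pseudocount) else matrix
  fit <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(fit$x))
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  coords <- data.frame(sample_id = colnames(matrix),
                       fit$x[, seq_len(k), drop = FALSE],
                       stringsAsFactors = FALSE, row.names = NULL)
  list(coordinates = coords, variance_explained = ve[seq_len(k)])
}
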