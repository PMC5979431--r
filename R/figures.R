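# internal: open a graphics device chosen by file extension
open_device <- function(path, width = 7, height = 5) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150,
                              type = if (capabilities("cairo")) "cairo" else NULL),
         svg = grDevices::svg(path, width = width, height = height),
         pdf = grDevices::pdf(path, width = width, height = height),
         stop("unsupported figure extension: ", ext))
  invisible(path)
}

#' Volcano-plot coordinates
#'
#' Per-gene (log2 fold change, -log10 p) pairs for the aging contrast.
#' Zero p-values are clamped to the smallest positive double before the
#' logarithm so coordinates stay finite.
#'
#' @param records A [fold_change_table()] result (columns fc_age, p_age).
#' @return Data.frame: gene, log2_fc, neg_log10_p.
#' @export
make_volcano_data <- function(records) {
  stopifnot(all(c("gene", "fc_age", "p_age") %in% colnames(records)))
  p <- pmax(records$p_age, .Machine$double.xmin)
  data.frame(gene = records$gene,
             log2_fc = log2(records$fc_age),
             neg_log10_p = -log10(p),
             stringsAsFactors = FALSE)
}

#' Drift plot: per-cohort box plots of pooled drift values
#'
#' Boxes appear in design order (young, aged, treated). The pooled drift
#' values are also written next to the figure as a TSV so the plot can be
#' regenerated from data alone; the aged-vs-young permutation p-value is
#' annotated when supplied.
#'
#' @param drift A [compute_drift()] result.
#' @param path Output figure path (.png, .svg or .pdf); a sibling
#'   `<path>.tsv` receives the plotted values.
#' @param test Optional [drift_variance_test()] result to annotate.
#' @param pool Pooling convention, as in [drift_variance_summary()].
#' @return `path`, invisibly.
#' @export
make_drift_plot <- function(drift, path, test = NULL, pool = "samples") {
  present <- intersect(cohort_levels(), unique(as.character(drift$samples$cohort)))
  if (length(present) < 2L) stop("drift plot needs >= 2 cohorts")
  long <- do.call(rbind, lapply(present, function(co) {
    data.frame(cohort = co, d = pooled_drift(drift, co, pool),
               stringsAsFactors = FALSE)
  }))
  long$cohort <- factor(long$cohort, levels = present)
  write_tsv_full(long, paste0(path, ".tsv"))
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$cohort, y = .data$d)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = NULL, y = expression(log[10] * "(expression / young reference)"),
                  title = sprintf("Transcriptional drift (%s)", drift$tissue)) +
    ggplot2::theme_classic()
  if (!is.null(test)) {
    gg <- gg + ggplot2::labs(subtitle = sprintf(
      "aged vs young drift-variance permutation p = %.4g", test$p))
  }
  open_device(path)
  print(gg)
  grDevices::dev.off()
  invisible(path)
}

#' Heatmap of z-scored expression for a gene list
#'
#' Rows are z-scored across the tissue's samples and ordered by
#' average-linkage hierarchical clustering on the Euclidean distance of
#' the z-scores; columns stay in design order. The plotted matrix is also
#' emitted as a TSV (in clustered order) so assertions run on data, never
#' pixels. Genes absent from the matrix are dropped with a warning.
#'
#' @param matrix Filtered RPKM matrix for one tissue.
#' @param genes Genes to display.
#' @param path Output figure path; `<path>.tsv` receives the values.
#' @return Invisible list with `values` (the z-scored, row-ordered matrix)
#'   and `order` (row order used).
#' @export
make_heatmap <- function(matrix, genes, path) {
  missing <- setdiff(genes, rownames(matrix))
  if (length(missing) > 0L) {
    warning("gene(s) absent from matrix omitted: ",
            paste(utils::head(missing, 10L), collapse = ", "))
  }
  genes <- intersect(genes, rownames(matrix))
  if (length(genes) == 0L) stop("no requested genes present in matrix")
  z <- row_zscore(matrix[genes, , drop = FALSE])
  ord <- if (nrow(z) > 2L) {
    stats::hclust(stats::dist(z, method = "euclidean"), method = "average")$order
  } else {
    seq_len(nrow(z))
  }
  z <- z[ord, , drop = FALSE]
  tsv <- data.frame(gene = rownames(z), z, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv_full(tsv, paste0(path, ".tsv"))
  long <- data.frame(
    gene = factor(rep(rownames(z), ncol(z)), levels = rev(rownames(z))),
    sample = factor(rep(colnames(z), each = nrow(z)), levels = colnames(z)),
    z = as.vector(z))
  gg <- ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$gene,
                                           fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  open_device(path, height = max(3, 0.18 * nrow(z) + 1.5))
  print(gg)
  grDevices::dev.off()
  invisible(list(values = z, order = ord))
}
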