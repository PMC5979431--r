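#' Run the full per-tissue analysis pipeline
#'
#' Orchestrates, for each requested tissue: load (or synthesize) the RPKM
#' matrix and sample sheet, validate, filter to the expressed universe,
#' fold-change classification, transcriptional drift with the
#' drift-variance permutation test, VZ/VC variance classification, PCA QC,
#' optional gene-set over-representation on the youthful gene selection,
#' and figure data. All tables are written tab-separated at full precision;
#' a JSON run manifest records every configurable value, the seed, package
#' version, and the gene counts at each stage. Identical configuration and
#' seed reproduce byte-identical tables.
#'
#' @param inputs Either a list with elements `matrix_path` and
#'   `samples_path` (paths to a TSV expression matrix and sample sheet) or
#'   a [synthetic_spec()], in which case data are generated per tissue.
#' @param outdir Output directory (created if needed).
#' @param config An [analysis_config()].
#' @param tissues Tissues to analyze (default both standard tissues when
#'   synthetic, the tissues present in the sheet when reading files).
#' @param gene_sets Optional named list of gene sets (e.g.
#'   [read_gene_sets()]) for over-representation of youthful genes.
#' @param force Run even when matrix/sheet sample ids mismatch (mismatched
#'   samples are dropped).
#' @return Invisible list of per-tissue result lists (filtered matrix,
#'   fold-change table, category counts, drift summaries, test results,
#'   variance records/counts, PCA, enrichment), plus the manifest.
#' @export
run_pipeline <- function(inputs, outdir, config = analysis_config(),
                         tissues = NULL, gene_sets = NULL, force = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  synthetic <- inherits(inputs, "txdrift_synthetic_spec")
  if (synthetic) {
    if (is.null(tissues)) tissues <- tissue_levels()
  } else {
    stopifnot(is.list(inputs), !is.null(inputs$matrix_path),
              !is.null(inputs$samples_path))
    full_matrix <- read_expression_matrix(inputs$matrix_path)
    full_samples <- read_sample_sheet(inputs$samples_path,
                                      cohort_map = config$cohort_map)
    report <- validate_dataset(full_matrix, full_samples)
    if (!report$ok && !force) {
      failed_marker(outdir, "validate",
                    "matrix/sample-sheet mismatch (use force = TRUE to drop)")
      stop("validate: matrix and sample sheet disagree; see report")
    }
    shared <- intersect(colnames(full_matrix), full_samples$sample_id)
    full_matrix <- full_matrix[, shared, drop = FALSE]
    full_samples <- full_samples[full_samples$sample_id %in% shared, , drop = FALSE]
    if (is.null(tissues)) {
      tissues <- intersect(tissue_levels(), unique(as.character(full_samples$tissue)))
    }
  }

  results <- list()
  stage_counts <- list()
  for (tissue in tissues) {
    tdir <- file.path(outdir, tissue)
    dir.create(tdir, showWarnings = FALSE, recursive = TRUE)
    res <- tryCatch(
      run_tissue(tissue, tdir, config, synthetic, inputs,
                 if (synthetic) NULL else full_matrix,
                 if (synthetic) NULL else full_samples,
                 gene_sets),
      error = function(e) {
        failed_marker(outdir, paste0("tissue:", tissue), conditionMessage(e))
        stop("stage failed for tissue '", tissue, "': ",
             conditionMessage(e), call. = FALSE)
      })
    results[[tissue]] <- res
    stage_counts[[tissue]] <- res$stage_counts
  }

  manifest <- list(
    package = "txdrift",
    version = as.character(utils::packageVersion("txdrift")),
    config = unclass(config),
    synthetic = synthetic,
    synthetic_spec = if (synthetic) unclass(inputs) else NULL,
    inputs = if (synthetic) NULL else inputs[c("matrix_path", "samples_path")],
    tissues = tissues,
    stage_counts = stage_counts
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

failed_marker <- function(outdir, stage, msg) {
  writeLines(c(stage, msg), file.path(outdir, "FAILED"))
}

# internal: one tissue, writes all artifacts into tdir
run_tissue <- function(tissue, tdir, config, synthetic, spec,
                       full_matrix, full_samples, gene_sets) {
  if (synthetic) {
    dat <- generate_dataset(spec, tissue)
    mat <- dat$matrix
    samples <- dat$samples
    write_expression_matrix(mat, file.path(tdir, "matrix.tsv"))
    write_tsv_full(samples, file.path(tdir, "samples.tsv"))
    write_tsv_full(dat$truth, file.path(tdir, "truth.tsv"))
  } else {
    mat <- full_matrix
    samples <- full_samples
    dat <- NULL
  }

  filtered <- filter_expressed(mat, samples, tissue, config$min_rpkm)
  if (nrow(filtered) == 0L) stop("filter: no genes pass min_rpkm = ", config$min_rpkm)
  write_expression_matrix(filtered, file.path(tdir, "filtered_matrix.tsv"))

  fc <- fold_change_table(filtered, samples, tissue, config)
  write_tsv_full(fc, file.path(tdir, "fold_change.tsv"))
  counts <- summarize_categories(fc, config)
  write_tsv_full(counts, file.path(tdir, "category_counts.tsv"))

  drift <- compute_drift(filtered, samples, tissue, "young")
  drift_long <- data.frame(
    gene = rep(rownames(drift$d), ncol(drift$d)),
    sample = rep(colnames(drift$d), each = nrow(drift$d)),
    d = as.vector(drift$d), stringsAsFactors = FALSE)
  write_tsv_full(drift_long, file.path(tdir, "drift_values.tsv"))
  present <- intersect(cohort_levels(), unique(as.character(samples$cohort[samples$tissue == tissue])))
  summaries <- do.call(rbind, lapply(present, function(co)
    drift_variance_summary(drift, co, config$drift_pool)))
  write_tsv_full(summaries, file.path(tdir, "drift_summary.tsv"))

  tests <- list(
    aged_vs_young = drift_variance_test(drift, "aged", "young",
                                        config$permutations, config$seed),
    aged_vs_treated = drift_variance_test(drift, "aged", "aged_treated",
                                          config$permutations, config$seed + 1L),
    treated_vs_young = drift_variance_test(drift, "aged_treated", "young",
                                           config$permutations, config$seed + 2L)
  )
  test_df <- data.frame(
    contrast = names(tests),
    observed = vapply(tests, `[[`, numeric(1L), "observed"),
    p = vapply(tests, `[[`, numeric(1L), "p"),
    permutations = vapply(tests, `[[`, integer(1L), "permutations"),
    stringsAsFactors = FALSE, row.names = NULL)
  write_tsv_full(test_df, file.path(tdir, "drift_tests.tsv"))

  variance <- classify_variance(filtered, samples, tissue, config)
  write_tsv_full(variance$records, file.path(tdir, "variance_records.tsv"))
  write_tsv_full(variance$counts, file.path(tdir, "variance_counts.tsv"))

  pca <- pca_qc(filtered, n_components = 2L, log2_transform = TRUE,
                pseudocount = config$pseudocount)
  pca_df <- pca$coordinates
  pca_df$variance_explained <- c(pca$variance_explained,
                                 rep(NA_real_, nrow(pca_df) - length(pca$variance_explained)))
  write_tsv_full(pca_df, file.path(tdir, "pca.tsv"))

  volcano <- make_volcano_data(fc)
  write_tsv_full(volcano, file.path(tdir, "volcano.tsv"))

  enrich <- NULL
  if (!is.null(gene_sets)) {
    selection <- fc$gene[fc$youthful]
    if (length(selection) > 0L) {
      enrich <- ora_hypergeometric(selection, fc$gene, gene_sets)
      write_tsv_full(enrich, file.path(tdir, "enrichment.tsv"))
    }
  }

  fig_ext <- if (capabilities("cairo")) "png" else "pdf"
  make_drift_plot(drift, file.path(tdir, paste0("drift_plot.", fig_ext)),
                  test = tests$aged_vs_young, pool = config$drift_pool)
  top <- fc$gene[order(fc$p_age)][seq_len(min(30L, nrow(fc)))]
  make_heatmap(filtered, top, file.path(tdir, paste0("heatmap.", fig_ext)))

  list(
    tissue = tissue,
    truth = if (synthetic) dat$truth else NULL,
    filtered = filtered,
    samples = samples,
    fold_change = fc,
    category_counts = counts,
    drift = drift,
    drift_summaries = summaries,
    drift_tests = test_df,
    variance = variance,
    pca = pca,
    enrichment = enrich,
    stage_counts = list(total_genes = nrow(mat),
                        filtered_genes = nrow(filtered),
                        changed_with_age = counts$change_with_age,
                        youthful = counts$if_more_youthful)
  )
}
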