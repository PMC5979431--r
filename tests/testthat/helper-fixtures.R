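# shared in-code fixtures: tiny matrices and the standard 3-cohort design

make_matrix <- function(values, genes = NULL, samples = NULL) {
  m <- if (is.matrix(values)) values else matrix(values, nrow = length(genes), byrow = TRUE)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  m
}

# 3 replicates per cohort, one tissue — the head design
head_sheet <- function(reps = 3L, tissue = "head") {
  cohorts <- cohort_levels()
  sample_sheet(
    sample_id = as.vector(vapply(cohorts, function(co)
      sprintf("%s_%s_r%d", tissue, co, seq_len(reps)), character(reps))),
    tissue = rep(tissue, 3L * reps),
    cohort = rep(cohorts, each = reps),
    replicate = rep(seq_len(reps), times = 3L)
  )
}

# a small complete dataset: n genes x (3 cohorts x reps), lognormal values > 1
random_dataset <- function(n = 8L, reps = 3L, seed = 1L, tissue = "head") {
  set.seed(seed)
  sheet <- head_sheet(reps, tissue)
  m <- make_matrix(matrix(exp(rnorm(n * nrow(sheet), 3, 0.5)), nrow = n),
                   genes = sprintf("g%02d", seq_len(n)),
                   samples = sheet$sample_id)
  list(matrix = m, samples = sheet)
}

write_matrix_file <- function(mat, sep = "\t") {
  path <- tempfile(fileext = if (sep == "\t") ".tsv" else ".csv")
  header <- paste(c("gene", colnames(mat)), collapse = sep)
  body <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i], format(mat[i, ], digits = 15)), collapse = sep),
    character(1L))
  writeLines(c(header, body), path)
  path
}

null_spec <- function(n_genes = 500L, seed = 1L, ...) {
  synthetic_spec(n_genes = n_genes, frac_age_up = 0, frac_age_down = 0,
                 frac_drift = 0, seed = seed, ...)
}
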