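#' Per-gene cohort mean expression
#'
#' Arithmetic mean RPKM across the replicates of one (tissue, cohort) group.
#'
#' @param matrix (Filtered) RPKM matrix.
#' @param samples Sample-sheet data.frame.
#' @param tissue,cohort Group selectors.
#' @return Named numeric vector of per-gene means.
#' @export
cohort_means <- function(matrix, samples, tissue, cohort) {
  ids <- intersect(samples_for(samples, tissue, cohort), colnames(matrix))
  if (length(ids) == 0L) {
    stop("no samples for tissue '", tissue, "', cohort '", cohort, "'")
  }
  rowMeans(matrix[, ids, drop = FALSE])
}

#' Per-gene fold change for a contrast
#'
#' The fold change is the linear ratio of cohort mean RPKM,
#' mean(numerator)/mean(denominator); fold cutoffs such as 1.4 act on this
#' ratio symmetrically (fc > c or fc < 1/c). `method = "geometric"` instead
#' returns the ratio of geometric means, 2^(mean log2 numerator - mean log2
#' denominator), for users who prefer averaging on the log scale.
#'
#' @param matrix Filtered RPKM matrix.
#' @param samples Sample-sheet data.frame.
#' @param contrast A [contrast_design()].
#' @param method "ratio" (default) or "geometric".
#' @return Named numeric vector of per-gene fold changes (strictly positive).
#' @export
fold_change_contrast <- function(matrix, samples, contrast,
                                 method = c("ratio", "geometric")) {
  method <- match.arg(method)
  if (method == "ratio") {
    num <- cohort_means(matrix, samples, contrast$tissue, contrast$numerator_cohort)
    den <- cohort_means(matrix, samples, contrast$tissue, contrast$denominator_cohort)
    if (any(den <= 0)) stop("nonpositive denominator cohort mean; filter the matrix first")
    num / den
  } else {
    lm2 <- log2_matrix(matrix, 0)
    num <- cohort_means(lm2, samples, contrast$tissue, contrast$numerator_cohort)
    den <- cohort_means(lm2, samples, contrast$tissue, contrast$denominator_cohort)
    2^(num - den)
  }
}

#' Per-gene differential-expression p-values for a contrast
#'
#' Welch's unequal-variance two-sample t test on log2 RPKM, two-sided,
#' computed gene-wise. This is the minimal defensible location test for
#' designs of 2-3 replicates per cohort; no moderation or shrinkage is
#' applied, and p-values are reported raw (a Benjamini-Hochberg column is
#' available downstream but never used for classification). Cohorts with a
#' single replicate yield NA with a warning; two replicates per cohort is
#' the supported minimum.
#'
#' @inheritParams fold_change_contrast
#' @param pseudocount Passed to [log2_matrix()].
#' @return Named numeric vector of two-sided p-values (NA when a cohort has
#'   fewer than 2 replicates or both groups are constant and equal).
#' @export
differential_test <- function(matrix, samples, contrast, pseudocount = 0) {
  ids_a <- intersect(samples_for(samples, contrast$tissue, contrast$numerator_cohort),
                     colnames(matrix))
  ids_b <- intersect(samples_for(samples, contrast$tissue, contrast$denominator_cohort),
                     colnames(matrix))
  if (length(ids_a) == 0L || length(ids_b) == 0L) {
    stop("empty cohort in contrast '", contrast$name, "'")
  }
  if (length(ids_a) < 2L || length(ids_b) < 2L) {
    warning("cohort with a single replicate in contrast '", contrast$name,
            "': p-values reported as NA")
    p <- rep(NA_real_, nrow(matrix))
    names(p) <- rownames(matrix)
    return(p)
  }
  lm2 <- log2_matrix(matrix, pseudocount)
  welch_rows(lm2[, ids_a, drop = FALSE], lm2[, ids_b, drop = FALSE])
}

# internal: vectorized Welch t test across matrix rows (two-sided p).
# Zero pooled variance with equal means gives t = 0/0; reported as p = 1
# (no evidence of a difference).
welch_rows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate & (m1 == m2)] <- 1
  p[degenerate & (m1 != m2)] <- 0
  names(p) <- rownames(a)
  p
}

#' Classify genes into fold-change categories
#'
#' Applies the strict fold cutoffs to the two contrasts:
#' \describe{
#'   \item{age_up / age_down}{fc_age = aged/young above `fc_age_cutoff`,
#'     resp. below its reciprocal.}
#'   \item{if_up / if_down}{fc_if = aged/treated — note the direction: the
#'     TREATED cohort is the denominator, so a gene whose expression is
#'     restored UPWARD by treatment (treated exceeds aged) has fc_if below
#'     1/`fc_if_cutoff` and is flagged `if_up`; fc_if above the cutoff
#'     means treated expression is lower than aged (`if_down`). This is the
#'     most error-prone sign convention in the design.}
#'   \item{youthful}{the treatment reverses the age direction:
#'     (age_down and if_up) or (age_up and if_down).}
#' }
#' All inequalities are strict, so a fold change exactly at a cutoff is not
#' flagged.
#'
#' @param records Data.frame with columns `gene`, `fc_age`, `fc_if` and
#'   optionally `p_age`, `p_if`.
#' @param config An [analysis_config()].
#' @return `records` with logical columns age_up, age_down, if_up, if_down,
#'   youthful appended.
#' @export
classify_genes <- function(records, config = analysis_config()) {
  stopifnot(all(c("gene", "fc_age", "fc_if") %in% colnames(records)))
  if (any(records$fc_age <= 0) || any(records$fc_if <= 0)) {
    stop("fold changes must be strictly positive")
  }
  ca <- config$fc_age_cutoff
  ci <- config$fc_if_cutoff
  records$age_up <- records$fc_age > ca
  records$age_down <- records$fc_age < 1 / ca
  records$if_down <- records$fc_if > ci
  records$if_up <- records$fc_if < 1 / ci
  records$youthful <- (records$age_down & records$if_up) |
    (records$age_up & records$if_down)
  records
}

#' Tally classified genes into category counts
#'
#' Column order follows the conventional report layout: total changed with
#' age, age down, age up, total changed with treatment, age-down-treatment-up,
#' age-up-treatment-down, and their sum ("more youthful"). By default the
#' treatment tally counts any gene beyond the treatment cutoff; with
#' `config$require_age_change` it is restricted to genes that also passed
#' the age cutoff.
#'
#' @param records Output of [classify_genes()].
#' @param config An [analysis_config()].
#' @return One-row data.frame of counts.
#' @export
summarize_categories <- function(records, config = analysis_config()) {
  needed <- c("age_up", "age_down", "if_up", "if_down", "youthful")
  stopifnot(all(needed %in% colnames(records)))
  if_hit <- records$if_up | records$if_down
  if (isTRUE(config$require_age_change)) {
    if_hit <- if_hit & (records$age_up | records$age_down)
  }
  data.frame(
    change_with_age = sum(records$age_up | records$age_down),
    age_down = sum(records$age_down),
    age_up = sum(records$age_up),
    change_with_if = sum(if_hit),
    age_down_if_up = sum(records$age_down & records$if_up),
    age_up_if_down = sum(records$age_up & records$if_down),
    if_more_youthful = sum(records$youthful)
  )
}

#' Full fold-change table for one tissue
#'
#' Convenience wrapper running both standard contrasts (aged/young and
#' aged/treated), the Welch test, classification, and a Benjamini-Hochberg
#' adjusted column per contrast (reported, never used for classification).
#'
#' @param matrix Filtered RPKM matrix for one tissue.
#' @param samples Sample-sheet data.frame.
#' @param tissue Tissue.
#' @param config An [analysis_config()].
#' @return Data.frame: gene, fc_age, log2_fc_age, p_age, padj_age, fc_if,
#'   log2_fc_if, p_if, padj_if, and the classification flags.
#' @export
fold_change_table <- function(matrix, samples, tissue,
                              config = analysis_config()) {
  c_age <- contrast_design("age", "aged", "young", tissue)
  c_if <- contrast_design("if", "aged", "aged_treated", tissue)
  fc_age <- fold_change_contrast(matrix, samples, c_age, method = config$fc_method)
  fc_if <- fold_change_contrast(matrix, samples, c_if, method = config$fc_method)
  p_age <- differential_test(matrix, samples, c_age, config$pseudocount)
  p_if <- differential_test(matrix, samples, c_if, config$pseudocount)
  records <- data.frame(
    gene = rownames(matrix),
    fc_age = unname(fc_age),
    log2_fc_age = unname(log2(fc_age)),
    p_age = unname(p_age),
    padj_age = unname(stats::p.adjust(p_age, method = "BH")),
    fc_if = unname(fc_if),
    log2_fc_if = unname(log2(fc_if)),
    p_if = unname(p_if),
    padj_if = unname(stats::p.adjust(p_if, method = "BH")),
    stringsAsFactors = FALSE
  )
  classify_genes(records, config)
}
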