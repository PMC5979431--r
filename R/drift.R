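#' Transcriptional drift against a young reference
#'
#' For each gene g and each sample s of the tissue, the drift value is
#' d(g, s) = log10( x(g, s) / reference mean of gene g ), where the
#' reference mean is the arithmetic mean over the reference (young) cohort's
#' replicates. Reference-cohort samples are included; their drift values are
#' centered near zero by construction. Drift is dimensionless and invariant
#' to any global rescaling of the matrix.
#'
#' @param matrix Filtered RPKM matrix for one tissue (all values > 0).
#' @param samples Sample-sheet data.frame.
#' @param tissue Tissue.
#' @param reference_cohort Cohort providing the per-gene reference means
#'   (default "young").
#' @return An object of class `txdrift_drift`: list with `d` (genes x
#'   samples matrix of drift values), `samples` (sheet rows for the tissue),
#'   `reference_cohort` and `tissue`.
#' @export
compute_drift <- function(matrix, samples, tissue, reference_cohort = "young") {
  ids <- intersect(samples_for(samples, tissue), colnames(matrix))
  if (length(ids) == 0L) stop("no samples for tissue '", tissue, "'")
  ref_mean <- cohort_means(matrix, samples, tissue, reference_cohort)
  if (any(ref_mean <= 0)) stop("reference cohort means must be positive; filter first")
  d <- log10(matrix[, ids, drop = FALSE] / ref_mean)
  structure(
    list(d = d,
         samples = samples[samples$sample_id %in% ids, , drop = FALSE],
         reference_cohort = reference_cohort,
         tissue = tissue),
    class = "txdrift_drift")
}

#' Drift-variance summary for one cohort
#'
#' Pools the drift values of every gene across all replicates of the cohort
#' and reports their variance (the transcriptional drift-variance, TD; n-1
#' convention) together with quartiles for drift plots. With
#' `pool = "cohort_mean"` the drift of the per-gene cohort mean is
#' summarized instead of per-sample values.
#'
#' @param drift A [compute_drift()] result.
#' @param cohort Cohort to summarize.
#' @param pool "samples" (default) or "cohort_mean".
#' @return One-row data.frame: cohort, n_genes, n_values, drift_variance,
#'   q1, median, q3.
#' @export
drift_variance_summary <- function(drift, cohort, pool = c("samples", "cohort_mean")) {
  pool <- match.arg(pool)
  pooled <- pooled_drift(drift, cohort, pool)
  if (length(pooled) == 0L) stop("no drift values for cohort '", cohort, "'")
  qs <- stats::quantile(pooled, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(
    cohort = cohort,
    n_genes = nrow(drift$d),
    n_values = length(pooled),
    drift_variance = if (length(pooled) > 1L) stats::var(pooled) else 0,
    q1 = qs[1L], median = qs[2L], q3 = qs[3L],
    stringsAsFactors = FALSE
  )
}

# internal: drift values of one cohort, pooled per the chosen convention
pooled_drift <- function(drift, cohort, pool = "samples") {
  ids <- drift$samples$sample_id[drift$samples$cohort == cohort]
  if (length(ids) == 0L) stop("cohort '", cohort, "' has no samples in drift table")
  block <- drift$d[, ids, drop = FALSE]
  if (pool == "cohort_mean") rowMeans(block) else as.vector(block)
}

#' Permutation test for a drift-variance difference between two cohorts
#'
#' Tests the null hypothesis that the two cohorts' pooled drift values are
#' equally dispersed. The statistic is |Var(pooled drift of a) - Var(pooled
#' drift of b)|. Because drift values are gene-wise dependent within a
#' sample, permutation is performed at the gene level: for each gene,
#' independently with probability 1/2, the gene's block of cohort-a drift
#' values is swapped with its cohort-b block, and the statistic recomputed.
#' p = (1 + number of permuted statistics >= observed) / (1 + permutations).
#' Deterministic given `seed`. A Brown-Forsythe test (one-way ANOVA on
#' absolute deviations from group medians) is available as a fast
#' parametric alternative.
#'
#' @param drift A [compute_drift()] result.
#' @param cohort_a,cohort_b Cohorts to compare.
#' @param permutations Number of permutations (>= 99 recommended).
#' @param seed Integer seed for the permutation stream.
#' @param method "permutation" (default) or "brown_forsythe".
#' @return List with `p`, `observed` (the statistic), `method`,
#'   `permutations`.
#' @export
drift_variance_test <- function(drift, cohort_a, cohort_b,
                                permutations = 999L, seed = 1L,
                                method = c("permutation", "brown_forsythe")) {
  method <- match.arg(method)
  ids_a <- drift$samples$sample_id[drift$samples$cohort == cohort_a]
  ids_b <- drift$samples$sample_id[drift$samples$cohort == cohort_b]
  if (length(ids_a) == 0L || length(ids_b) == 0L) stop("empty cohort")
  da <- drift$d[, ids_a, drop = FALSE]
  db <- drift$d[, ids_b, drop = FALSE]

  if (method == "brown_forsythe") {
    xa <- as.vector(da); xb <- as.vector(db)
    za <- abs(xa - stats::median(xa))
    zb <- abs(xb - stats::median(xb))
    fit <- stats::oneway.test(z ~ g, data = data.frame(
      z = c(za, zb), g = factor(rep(c("a", "b"), c(length(za), length(zb))))))
    return(list(p = fit$p.value,
                observed = abs(stats::var(xa) - stats::var(xb)),
                method = method, permutations = 0L))
  }

  # pooled variance from per-gene row sums / sums of squares so each
  # permutation costs O(n_genes) vector arithmetic
  pooled_var <- function(s, ss, n) (sum(ss) - sum(s)^2 / n) / (n - 1)
  sa <- rowSums(da); ssa <- rowSums(da^2); na <- length(da)
  sb <- rowSums(db); ssb <- rowSums(db^2); nb <- length(db)
  observed <- abs(pooled_var(sa, ssa, na) - pooled_var(sb, ssb, nb))

  if (identical(sort(ids_a), sort(ids_b))) {
    return(list(p = 1, observed = 0, method = method,
                permutations = as.integer(permutations)))
  }

  set.seed(seed)
  g <- nrow(drift$d)
  ca <- ncol(da); cb <- ncol(db)  # per-gene block widths (may differ)
  exceed <- 0L
  for (i in seq_len(permutations)) {
    swap <- stats::runif(g) < 0.5
    k <- sum(swap)
    s_a <- ifelse(swap, sb, sa); ss_a <- ifelse(swap, ssb, ssa)
    s_b <- ifelse(swap, sa, sb); ss_b <- ifelse(swap, ssa, ssb)
    n_a <- (g - k) * ca + k * cb
    n_b <- (g - k) * cb + k * ca
    stat <- abs(pooled_var(s_a, ss_a, n_a) - pooled_var(s_b, ss_b, n_b))
    if (stat >= observed) exceed <- exceed + 1L
  }
  list(p = (1 + exceed) / (1 + permutations), observed = observed,
       method = method, permutations = as.integer(permutations))
}

#' Per-gene variance Z scores (VZ) for one cohort
#'
#' VZ is the coefficient of variation of a gene's replicate RPKM within a
#' cohort: SD/mean, with the sample (n-1) SD. For the two-replicate case
#' this reduces to |x1 - x2| / (sqrt(2) * mean).
#'
#' @param matrix Filtered RPKM matrix.
#' @param samples Sample-sheet data.frame.
#' @param tissue,cohort Group selectors (>= 2 replicates required).
#' @return Named numeric vector of per-gene VZ values (>= 0).
#' @export
compute_vz <- function(matrix, samples, tissue, cohort) {
  ids <- intersect(samples_for(samples, tissue, cohort), colnames(matrix))
  if (length(ids) < 2L) {
    stop("cohort '", cohort, "' has fewer than 2 replicates; VZ undefined")
  }
  block <- matrix[, ids, drop = FALSE]
  mu <- rowMeans(block)
  sdv <- sqrt(rowSums((block - mu)^2) / (length(ids) - 1))
  sdv / mu
}

#' Per-gene variance change (VC) between two cohorts
#'
#' The ratio of VZ values, regularized with a small epsilon on numerator
#' and denominator so that a zero replicate SD yields a finite ratio; a
#' gene with VZ = 0 in both cohorts gets VC = 1 exactly.
#'
#' @param vz_a,vz_b Per-gene VZ vectors (same genes, same order).
#' @param epsilon Regularizer (default 1e-6).
#' @return Numeric vector of VC values (> 0).
#' @export
variance_change <- function(vz_a, vz_b, epsilon = 1e-6) {
  if (any(vz_a < 0) || any(vz_b < 0)) stop("VZ values must be nonnegative")
  stopifnot(length(vz_a) == length(vz_b), epsilon > 0)
  vc <- (vz_a + epsilon) / (vz_b + epsilon)
  vc[vz_a == 0 & vz_b == 0] <- 1
  vc
}

#' Variance-change classification across the three standard contrasts
#'
#' Computes VZ per cohort and VC for the contrasts aged/young, aged/treated
#' and young/treated, flags genes with VC strictly above `config$vc_cutoff`,
#' and tallies counts per contrast.
#'
#' @param matrix Filtered RPKM matrix for one tissue.
#' @param samples Sample-sheet data.frame.
#' @param tissue Tissue.
#' @param config An [analysis_config()].
#' @return List with `records` (per-gene data.frame: gene, vz_young,
#'   vz_aged, vz_treated, vc_aged_vs_young, vc_aged_vs_treated,
#'   vc_young_vs_treated and high_vc_* flags) and `counts` (one-row
#'   data.frame of per-contrast tallies).
#' @export
classify_variance <- function(matrix, samples, tissue,
                              config = analysis_config()) {
  vz <- list(
    young = compute_vz(matrix, samples, tissue, "young"),
    aged = compute_vz(matrix, samples, tissue, "aged"),
    aged_treated = compute_vz(matrix, samples, tissue, "aged_treated")
  )
  eps <- config$vc_epsilon
  vc_ay <- variance_change(vz$aged, vz$young, eps)
  vc_at <- variance_change(vz$aged, vz$aged_treated, eps)
  vc_yt <- variance_change(vz$young, vz$aged_treated, eps)
  cut <- config$vc_cutoff
  records <- data.frame(
    gene = rownames(matrix),
    vz_young = unname(vz$young),
    vz_aged = unname(vz$aged),
    vz_treated = unname(vz$aged_treated),
    vc_aged_vs_young = unname(vc_ay),
    vc_aged_vs_treated = unname(vc_at),
    vc_young_vs_treated = unname(vc_yt),
    high_vc_aged_vs_young = unname(vc_ay > cut),
    high_vc_aged_vs_treated = unname(vc_at > cut),
    high_vc_young_vs_treated = unname(vc_yt > cut),
    stringsAsFactors = FALSE
  )
  counts <- data.frame(
    aged_vs_young = sum(records$high_vc_aged_vs_young),
    aged_vs_treated = sum(records$high_vc_aged_vs_treated),
    young_vs_treated = sum(records$high_vc_young_vs_treated)
  )
  list(records = records, counts = counts)
}

#' Scaled VZ profiles for scatter display
#'
#' For a list of genes and a pair of cohorts, each gene's VZ in each cohort
#' is divided by that gene's maximum VZ across the two cohorts, so the
#' larger cohort maps to exactly 1 and values lie in (0, 1]. Genes with
#' VZ = 0 in both cohorts are emitted as (1, 1) with a warning.
#'
#' @param vz_a,vz_b Named per-gene VZ vectors for the two cohorts.
#' @param genes Genes to profile (subset of names(vz_a)).
#' @return Data.frame: gene, scaled_a, scaled_b.
#' @export
scaled_vz_profile <- function(vz_a, vz_b, genes = names(vz_a)) {
  missing <- setdiff(genes, intersect(names(vz_a), names(vz_b)))
  if (length(missing) > 0L) {
    stop("gene(s) without VZ values: ", paste(utils::head(missing, 5L), collapse = ", "))
  }
  a <- vz_a[genes]; b <- vz_b[genes]
  mx <- pmax(a, b)
  zero <- mx == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with VZ = 0 in both cohorts emitted as (1, 1)")
    mx[zero] <- 1
    a[zero] <- 1; b[zero] <- 1
  }
  data.frame(gene = genes, scaled_a = unname(a / mx), scaled_b = unname(b / mx),
             stringsAsFactors = FALSE)
}
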