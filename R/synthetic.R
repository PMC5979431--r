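#' Specification for a synthetic replicate-RPKM dataset
#'
#' The generator emulates the statistical structure of a three-arm aging
#' RNA-seq design: log-normal baseline expression across genes, a planted
#' subset of age-responsive genes (up and down by a common fold), a subset
#' of those restored to the young mean by treatment, and age-dependent
#' inflation of between-replicate dispersion ("drift") that treatment only
#' partially suppresses. Replicate values are the true cohort mean times a
#' unit-mean log-normal noise factor whose coefficient of variation is
#' cv(gene, cohort), so RPKM stay positive and CV statistics are natural.
#'
#' Defaults mirror the published study design: 3 replicates per cohort
#' (heads; thoraces used 2), ~12% age-responsive genes out of ~10,000
#' (about 1200, matching the reported per-tissue counts), a 2-fold age
#' effect (comfortably beyond the 1.4 cutoff), ~20% of responsive genes
#' restored by treatment, ~15% of genes drifting with a 4-fold CV inflation
#' in aged tissue reduced to 1.5-fold under treatment, and a baseline
#' between-replicate CV of 0.2.
#'
#' @param n_genes Number of genes.
#' @param replicates_per_cohort Named integer vector over
#'   [cohort_levels()].
#' @param baseline_log_mean,baseline_log_sd Natural-log location and scale
#'   of the baseline RPKM distribution across genes.
#' @param frac_age_up,frac_age_down Fractions of genes planted up/down with
#'   age (sum must be <= 1).
#' @param age_effect_fold Fold applied to the young mean in aged cohorts
#'   (multiplied for up genes, divided for down genes).
#' @param frac_restored Fraction of age-responsive genes (within each
#'   direction) whose treated mean returns to the young mean; the rest keep
#'   the aged mean.
#' @param frac_drift Fraction of genes with inflated aged dispersion.
#' @param base_cv Between-replicate coefficient of variation in the young
#'   cohort (and for non-drift genes everywhere).
#' @param drift_cv_factor CV multiplier in the aged cohort for drift genes.
#' @param treatment_cv_factor CV multiplier in the treated cohort for drift
#'   genes; must lie in [1, drift_cv_factor].
#' @param seed Integer seed; identical (spec, tissue) pairs reproduce
#'   bit-identical datasets.
#' @return An object of class `txdrift_synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 10000L,
                           replicates_per_cohort = c(young = 3L, aged = 3L,
                                                     aged_treated = 3L),
                           baseline_log_mean = log(20),
                           baseline_log_sd = 1.5,
                           frac_age_up = 0.06,
                           frac_age_down = 0.06,
                           age_effect_fold = 2.0,
                           frac_restored = 0.2,
                           frac_drift = 0.15,
                           base_cv = 0.2,
                           drift_cv_factor = 4.0,
                           treatment_cv_factor = 1.5,
                           seed = 1L) {
  stopifnot(
    n_genes >= 1L,
    all(cohort_levels() %in% names(replicates_per_cohort)),
    all(replicates_per_cohort >= 1L),
    baseline_log_sd > 0,
    frac_age_up >= 0, frac_age_down >= 0, frac_age_up + frac_age_down <= 1,
    age_effect_fold > 1,
    frac_restored >= 0, frac_restored <= 1,
    frac_drift >= 0, frac_drift <= 1,
    base_cv >= 0,
    drift_cv_factor >= 1,
    treatment_cv_factor >= 1, treatment_cv_factor <= drift_cv_factor
  )
  spec <- list(
    n_genes = as.integer(n_genes),
    replicates_per_cohort = replicates_per_cohort[cohort_levels()],
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    frac_age_up = frac_age_up,
    frac_age_down = frac_age_down,
    age_effect_fold = age_effect_fold,
    frac_restored = frac_restored,
    frac_drift = frac_drift,
    base_cv = base_cv,
    drift_cv_factor = drift_cv_factor,
    treatment_cv_factor = treatment_cv_factor,
    seed = as.integer(seed)
  )
  class(spec) <- "txdrift_synthetic_spec"
  spec
}

# unit-mean multiplicative log-normal noise, vectorized over per-gene cv:
# sigma^2 = log(1 + cv^2), mu = -sigma^2/2 so E[noise] = 1 exactly
# (cv = 0 yields sd 0, hence a noise factor of exactly 1).
lognormal_noise <- function(cv) {
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(length(cv), mean = -s2 / 2, sd = sqrt(s2)))
}

#' Generate a synthetic replicate RPKM dataset with known truth
#'
#' Planted gene assignment is a deterministic slice of a seeded permutation
#' of gene indices, so fractions yield exact counts: the first
#' `round(frac_age_up * n)` permuted genes go up with age, the next
#' `round(frac_age_down * n)` go down; within each direction the first
#' `round(frac_restored * k)` are restored by treatment. Drift genes are a
#' slice of an independent permutation and may overlap age-responsive
#' genes, as in real tissue.
#'
#' @param spec A [synthetic_spec()].
#' @param tissue Tissue label for the emitted samples; also offsets the RNG
#'   stream so each tissue in a design gets distinct data.
#' @return A list with elements `matrix` (genes x samples RPKM), `samples`
#'   (sample-sheet data.frame) and `truth` (per-gene truth table with flag
#'   columns is_age_up, is_age_down, is_restored, is_drift, true means and
#'   true CVs per cohort).
#' @examples
#' d <- generate_dataset(synthetic_spec(n_genes = 100, seed = 7), "head")
#' dim(d$matrix)
#' @export
generate_dataset <- function(spec, tissue = "head") {
  stopifnot(inherits(spec, "txdrift_synthetic_spec"))
  tissue_idx <- match(tissue, tissue_levels())
  if (is.na(tissue_idx)) tissue_idx <- 1L + (sum(utf8ToInt(tissue)) %% 7L)
  seed_used <- (spec$seed + 1000003L * (tissue_idx - 1L)) %% .Machine$integer.max
  set.seed(seed_used)

  n <- spec$n_genes
  genes <- sprintf("g%05d", seq_len(n))

  perm <- sample.int(n)
  n_up <- round(spec$frac_age_up * n)
  n_down <- round(spec$frac_age_down * n)
  up_idx <- perm[seq_len(n_up)]
  down_idx <- perm[n_up + seq_len(n_down)]
  restored_idx <- c(up_idx[seq_len(round(spec$frac_restored * n_up))],
                    down_idx[seq_len(round(spec$frac_restored * n_down))])
  perm2 <- sample.int(n)
  drift_idx <- perm2[seq_len(round(spec$frac_drift * n))]

  is_up <- is_down <- is_restored <- is_drift <- rep(FALSE, n)
  is_up[up_idx] <- TRUE
  is_down[down_idx] <- TRUE
  is_restored[restored_idx] <- TRUE
  is_drift[drift_idx] <- TRUE

  young_mean <- exp(stats::rnorm(n, spec$baseline_log_mean, spec$baseline_log_sd))
  aged_mean <- young_mean
  aged_mean[is_up] <- young_mean[is_up] * spec$age_effect_fold
  aged_mean[is_down] <- young_mean[is_down] / spec$age_effect_fold
  treated_mean <- aged_mean
  treated_mean[is_restored] <- young_mean[is_restored]

  cv_young <- rep(spec$base_cv, n)
  cv_aged <- ifelse(is_drift, spec$base_cv * spec$drift_cv_factor, spec$base_cv)
  cv_treated <- ifelse(is_drift, spec$base_cv * spec$treatment_cv_factor, spec$base_cv)

  means <- cbind(young = young_mean, aged = aged_mean, aged_treated = treated_mean)
  cvs <- cbind(young = cv_young, aged = cv_aged, aged_treated = cv_treated)

  reps <- spec$replicates_per_cohort
  cohort_labels <- c(young = "1W", aged = "4W", aged_treated = "4W-IF")
  cols <- list()
  sheet <- list()
  for (cohort in cohort_levels()) {
    for (r in seq_len(reps[[cohort]])) {
      sid <- sprintf("%s_%s_r%d", tissue, cohort_labels[[cohort]], r)
      cols[[sid]] <- means[, cohort] * lognormal_noise(cvs[, cohort])
      sheet[[sid]] <- data.frame(sample_id = sid, tissue = tissue,
                                 cohort = cohort, replicate = r,
                                 stringsAsFactors = FALSE)
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- genes
  samples <- do.call(rbind, sheet)
  rownames(samples) <- NULL
  samples$cohort <- factor(samples$cohort, levels = cohort_levels())
  samples$tissue <- factor(samples$tissue,
                           levels = union(tissue_levels(), tissue))

  truth <- data.frame(
    gene = genes,
    is_age_up = is_up,
    is_age_down = is_down,
    is_restored = is_restored,
    is_drift = is_drift,
    true_young_mean = young_mean,
    true_aged_mean = aged_mean,
    true_treated_mean = treated_mean,
    true_cv_young = cv_young,
    true_cv_aged = cv_aged,
    true_cv_treated = cv_treated,
    stringsAsFactors = FALSE
  )
  list(matrix = mat, samples = samples, truth = truth)
}

#' Noise-free category counts implied by a truth table
#'
#' Classifies each gene from its TRUE cohort means using the configured
#' fold cutoffs — the recovery baseline that a noise-free classifier would
#' report, in the same schema as [summarize_categories()].
#'
#' @param truth Truth table from [generate_dataset()].
#' @param config An [analysis_config()].
#' @return A one-row data.frame of category counts.
#' @export
expected_category_counts <- function(truth, config = analysis_config()) {
  fc_age <- truth$true_aged_mean / truth$true_young_mean
  fc_if <- truth$true_aged_mean / truth$true_treated_mean
  records <- classify_genes(
    data.frame(gene = truth$gene, fc_age = fc_age, fc_if = fc_if,
               stringsAsFactors = FALSE),
    config)
  summarize_categories(records, config)
}
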