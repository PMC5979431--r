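#' Canonical cohort and tissue vocabularies
#'
#' Cohorts follow the common three-arm aging design: a young reference, an
#' aged (middle-aged) group, and an aged group that received an
#' intermittent-fasting style treatment. Input files may use the field's
#' shorthand labels ("1W", "4W", "4W-IF"); [default_cohort_map()] translates
#' them to the canonical levels.
#'
#' @return Character vector of canonical cohort levels, in design order.
#' @export
cohort_levels <- function() c("young", "aged", "aged_treated")

#' @rdname cohort_levels
#' @export
tissue_levels <- function() c("head", "thorax")

#' Default mapping from file labels to canonical cohort levels
#'
#' @return Named character vector: names are labels accepted in sample
#'   sheets, values are canonical cohort levels.
#' @export
default_cohort_map <- function() {
  c("1W" = "young", "4W" = "aged", "4W-IF" = "aged_treated",
    "young" = "young", "aged" = "aged", "aged_treated" = "aged_treated")
}

#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline. Defaults follow the
#' published three-arm Drosophila design: genes expressed at more than
#' `min_rpkm` RPKM in every sample of a tissue form the analysis universe;
#' age-responsive genes exceed a symmetric `fc_age_cutoff`-fold change
#' (aged/young), treatment-responsive genes a `fc_if_cutoff`-fold change
#' (aged/treated); genes whose replicate coefficient of variation (variance
#' Z score, VZ = SD/mean) changes more than `vc_cutoff`-fold between cohorts
#' are flagged as high variance change.
#'
#' @param min_rpkm Expression filter: a gene is retained only when strictly
#'   above this RPKM value in every sample of the tissue. Default 1.0.
#' @param fc_age_cutoff Fold cutoff for the aged/young contrast (strict,
#'   applied symmetrically: fc > cutoff or fc < 1/cutoff). Default 1.4.
#' @param fc_if_cutoff Fold cutoff for the aged/treated contrast. Default 1.3.
#' @param vc_cutoff Variance-change cutoff on VZ ratios (strict). Default
#'   3.75; 3.5 is the alternative used for proteolytic gene sets.
#' @param pseudocount Added before log2 transformation. Default 0: the
#'   strictly-greater-than-1 RPKM filter precedes every logarithm, so zeros
#'   cannot reach it.
#' @param seed Integer seed used by stochastic steps (permutation test,
#'   synthetic data).
#' @param permutations Number of permutations for the drift-variance test.
#' @param fc_method "ratio" (linear ratio of cohort mean RPKM; default) or
#'   "geometric" (ratio of geometric means, i.e. 2^difference of mean log2).
#' @param vc_epsilon Regularizer added to numerator and denominator of VZ
#'   ratios so zero replicate SDs cannot produce infinities.
#' @param drift_pool "samples" (default: per-sample drift values pooled over
#'   genes and replicates) or "cohort_mean" (drift of the cohort mean).
#' @param require_age_change If TRUE, the "change with IF" tally only counts
#'   genes that also pass the age cutoff. Default FALSE (independent counts).
#' @param cohort_map Named character vector mapping sample-sheet labels to
#'   canonical cohort levels.
#'
#' @return An object of class `txdrift_config` (a validated list).
#' @examples
#' cfg <- analysis_config()
#' cfg$fc_age_cutoff
#' @export
analysis_config <- function(min_rpkm = 1.0,
                            fc_age_cutoff = 1.4,
                            fc_if_cutoff = 1.3,
                            vc_cutoff = 3.75,
                            pseudocount = 0,
                            seed = 1L,
                            permutations = 999L,
                            fc_method = c("ratio", "geometric"),
                            vc_epsilon = 1e-6,
                            drift_pool = c("samples", "cohort_mean"),
                            require_age_change = FALSE,
                            cohort_map = default_cohort_map()) {
  fc_method <- match.arg(fc_method)
  drift_pool <- match.arg(drift_pool)
  stopifnot(
    is.numeric(min_rpkm), length(min_rpkm) == 1L, min_rpkm > 0,
    is.numeric(fc_age_cutoff), fc_age_cutoff > 1,
    is.numeric(fc_if_cutoff), fc_if_cutoff > 1,
    is.numeric(vc_cutoff), vc_cutoff > 1,
    is.numeric(pseudocount), pseudocount >= 0,
    is.numeric(vc_epsilon), vc_epsilon > 0,
    is.numeric(permutations), permutations >= 1
  )
  cfg <- list(
    min_rpkm = min_rpkm,
    fc_age_cutoff = fc_age_cutoff,
    fc_if_cutoff = fc_if_cutoff,
    vc_cutoff = vc_cutoff,
    pseudocount = pseudocount,
    seed = as.integer(seed),
    permutations = as.integer(permutations),
    fc_method = fc_method,
    vc_epsilon = vc_epsilon,
    drift_pool = drift_pool,
    require_age_change = isTRUE(require_age_change),
    cohort_map = cohort_map
  )
  class(cfg) <- "txdrift_config"
  cfg
}

#' Read an analysis configuration from a YAML file
#'
#' Every field of [analysis_config()] may appear as a top-level key; absent
#' keys keep their defaults. Unknown keys are an error, so typos do not
#' silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `txdrift_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$cohort_map)) raw$cohort_map <- unlist(raw$cohort_map)
  do.call(analysis_config, raw)
}

#' @export
print.txdrift_config <- function(x, ...) {
  cat("txdrift analysis configuration\n")
  for (k in setdiff(names(x), "cohort_map")) {
    cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  }
  invisible(x)
}

#' Define a two-cohort contrast within one tissue
#'
#' @param name Short label, e.g. "age" or "if".
#' @param numerator_cohort,denominator_cohort Canonical cohort levels; the
#'   fold change is mean(numerator)/mean(denominator). The aging contrast is
#'   aged/young, the treatment contrast aged/aged_treated.
#' @param tissue Tissue the contrast is computed in.
#' @return An object of class `txdrift_contrast`.
#' @examples
#' contrast_design("age", "aged", "young", "head")
#' @export
contrast_design <- function(name, numerator_cohort, denominator_cohort, tissue) {
  stopifnot(is.character(name), length(name) == 1L)
  if (identical(numerator_cohort, denominator_cohort)) {
    stop("contrast numerator and denominator cohorts must differ")
  }
  structure(
    list(name = name,
         numerator_cohort = numerator_cohort,
         denominator_cohort = denominator_cohort,
         tissue = tissue),
    class = "txdrift_contrast"
  )
}
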