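test_that("drift values are log10 ratios to the young reference mean", {
  sheet <- head_sheet(1)
  m <- make_matrix(matrix(c(20, 200, 20,
                            5, 5, 50), nrow = 2, byrow = TRUE),
                   genes = c("a", "b"), samples = sheet$sample_id)
  dr <- compute_drift(m, sheet, "head")
  aged_id <- sheet$sample_id[sheet$cohort == "aged"]
  treated_id <- sheet$sample_id[sheet$cohort == "aged_treated"]
  expect_equal(unname(dr$d["a", aged_id]), 1.0)        # log10(200/20)
  expect_equal(unname(dr$d["a", treated_id]), 0.0)     # equals reference mean
  expect_equal(unname(dr$d["b", treated_id]), 1.0)
  # single-replicate reference: its own drift is exactly 0
  young_id <- sheet$sample_id[sheet$cohort == "young"]
  expect_equal(unname(dr$d[, young_id]), c(0, 0))
  expect_equal(drift_variance_summary(dr, "young")$drift_variance, 0)

  # global rescaling leaves drift unchanged
  dr2 <- compute_drift(m * 100, sheet, "head")
  expect_equal(dr2$d, dr$d, tolerance = 1e-12)
})

test_that("drift-variance summary pools values with the n-1 convention", {
  sheet <- head_sheet(1)
  # aged sample engineered so pooled aged drift values are {0, 1}
  m <- make_matrix(matrix(c(10, 10, 10,
                            10, 100, 10), nrow = 2, byrow = TRUE),
                   genes = c("a", "b"), samples = sheet$sample_id)
  dr <- compute_drift(m, sheet, "head")
  s <- drift_variance_summary(dr, "aged")
  expect_equal(s$drift_variance, 0.5)  # var({0, 1}) with n-1
  expect_equal(s$n_values, 2L)

  # scaling one aged sample shifts its drift by log10(c), variance within
  # that sample unchanged
  m2 <- m
  aged_id <- sheet$sample_id[sheet$cohort == "aged"]
  m2[, aged_id] <- m2[, aged_id] * 10
  dr_shift <- compute_drift(m2, sheet, "head")
  expect_equal(dr_shift$d[, aged_id], dr$d[, aged_id] + 1, tolerance = 1e-12)
  expect_equal(var(dr_shift$d[, aged_id]), var(dr$d[, aged_id]), tolerance = 1e-12)
})

test_that("permutation test is deterministic, null-identical on self-comparison", {
  d <- random_dataset(n = 60, seed = 61)
  dr <- compute_drift(d$matrix, d$samples, "head")
  self <- drift_variance_test(dr, "aged", "aged", permutations = 99, seed = 1)
  expect_equal(self$p, 1)
  expect_equal(self$observed, 0)

  t1 <- drift_variance_test(dr, "aged", "aged_treated", permutations = 199, seed = 9)
  t2 <- drift_variance_test(dr, "aged", "aged_treated", permutations = 199, seed = 9)
  expect_identical(t1, t2)
  expect_gte(t1$p, 1 / 200)
  # Brown-Forsythe alternative returns a probability
  bf <- drift_variance_test(dr, "aged", "aged_treated", method = "brown_forsythe")
  expect_true(bf$p >= 0 && bf$p <= 1)
})

test_that("drift separates synthetic cohorts with the planted ordering", {
  ok_order <- 0L; ok_p <- 0L
  for (s in 1:5) {
    spec <- synthetic_spec(n_genes = 2000, drift_cv_factor = 4,
                           treatment_cv_factor = 1.5, seed = 700 + s)
    d <- generate_dataset(spec, "head")
    f <- filter_expressed(d$matrix, d$samples, "head", 1)
    dr <- compute_drift(f, d$samples, "head")
    tv <- vapply(cohort_levels(), function(co)
      drift_variance_summary(dr, co)$drift_variance, numeric(1))
    if (tv["young"] < tv["aged_treated"] && tv["aged_treated"] < tv["aged"]) {
      ok_order <- ok_order + 1L
    }
    p <- drift_variance_test(dr, "aged", "young", permutations = 999, seed = s)$p
    if (p <= 0.001) ok_p <- ok_p + 1L
  }
  expect_gte(ok_order, 4L)
  expect_equal(ok_p, 5L)
})

test_that("VZ is the n-1 coefficient of variation with exact small cases", {
  sheet <- head_sheet(3)
  m <- make_matrix(matrix(c(1, 2, 3, rep(9, 6),
                            5, 5, 5, rep(9, 6)), nrow = 2, byrow = TRUE),
                   genes = c("a", "b"), samples = sheet$sample_id)
  vz <- compute_vz(m, sheet, "head", "young")
  expect_equal(unname(vz), c(0.5, 0))   # mean 2, sd 1; constant -> 0
  expect_equal(compute_vz(m * 1000, sheet, "head", "young"), vz, tolerance = 1e-12)

  solo <- sheet[sheet$replicate == 1 & sheet$cohort == "young", ]
  expect_error(compute_vz(m[, solo$sample_id, drop = FALSE], solo, "head", "young"),
               "fewer than 2")

  # n = 2 convention: SD = |x1 - x2| / sqrt(2)
  duo <- head_sheet(2)
  m2 <- make_matrix(matrix(c(10, 30, rep(1, 4)), nrow = 1),
                    genes = "a", samples = duo$sample_id)
  expect_equal(unname(compute_vz(m2, duo, "head", "young")),
               (20 / sqrt(2)) / 20)
})

test_that("VC regularizes zeros and flags strictly above the cutoff", {
  expect_equal(variance_change(0.3, 0.3), 1.0)
  expect_equal(variance_change(0, 0), 1.0)
  expect_equal(variance_change(0.8, 0.2), (0.8 + 1e-6) / (0.2 + 1e-6))
  expect_gt(variance_change(0.8, 0.2), 3.75)
  expect_error(variance_change(-0.1, 0.2), "nonnegative")
  expect_true(is.finite(variance_change(0.5, 0)))

  # strict cutoff: a VC of exactly 3.75 is not flagged
  sheet <- head_sheet(3)
  set.seed(71)
  m <- make_matrix(matrix(rlnorm(20 * 9, 3, 0.4), nrow = 20),
                   samples = sheet$sample_id)
  cls <- classify_variance(m, sheet, "head", analysis_config())
  expect_identical(cls$records$high_vc_aged_vs_treated,
                   cls$records$vc_aged_vs_treated > 3.75)
  expect_equal(cls$counts$aged_vs_young,
               sum(cls$records$vc_aged_vs_young > 3.75))
  # alternative 3.5 cutoff is configurable
  cls35 <- classify_variance(m, sheet, "head", analysis_config(vc_cutoff = 3.5))
  expect_equal(cls35$counts$aged_vs_treated,
               sum(cls$records$vc_aged_vs_treated > 3.5))
})

test_that("VZ/VC match an independent direct-formula recomputation to 1e-12", {
  sheet <- head_sheet(2)
  set.seed(81)
  m <- make_matrix(matrix(rlnorm(10 * 6, 2, 0.6), nrow = 10),
                   samples = sheet$sample_id)
  for (co in cohort_levels()) {
    ids <- sheet$sample_id[sheet$cohort == co]
    direct <- vapply(seq_len(10), function(g) {
      x <- m[g, ids]
      sqrt(sum((x - mean(x))^2) / (length(x) - 1)) / mean(x)
    }, numeric(1))
    expect_equal(unname(compute_vz(m, sheet, "head", co)), direct,
                 tolerance = 1e-12)
  }
  vz_a <- compute_vz(m, sheet, "head", "aged")
  vz_b <- compute_vz(m, sheet, "head", "aged_treated")
  expect_equal(variance_change(vz_a, vz_b, 1e-6),
               (vz_a + 1e-6) / (vz_b + 1e-6), tolerance = 1e-12)
})

test_that("scaled VZ profiles normalize each gene to its cross-cohort maximum", {
  vz_a <- c(g1 = 0.8, g2 = 0.4, g3 = 0)
  vz_b <- c(g1 = 0.2, g2 = 0.4, g3 = 0)
  expect_warning(prof <- scaled_vz_profile(vz_a, vz_b), "VZ = 0")
  expect_equal(prof$scaled_a, c(1.0, 1.0, 1.0))
  expect_equal(prof$scaled_b, c(0.25, 1.0, 1.0))
  expect_true(all(prof$scaled_a > 0 & prof$scaled_a <= 1))
  expect_error(scaled_vz_profile(vz_a, vz_b[1:2], genes = names(vz_a)),
               "without VZ")
})
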