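test_that("cohort means are plain replicate averages, invariant to replicate order", {
  sheet <- head_sheet(3)
  m <- make_matrix(matrix(c(10, 20, 30, rep(1, 6),
                            7, 7, 7, rep(2, 6)), nrow = 2, byrow = TRUE),
                   genes = c("a", "b"), samples = sheet$sample_id)
  mu <- cohort_means(m, sheet, "head", "young")
  expect_equal(unname(mu), c(20, 7))
  perm <- m[, sample(colnames(m)), drop = FALSE]
  expect_equal(cohort_means(perm, sheet, "head", "young"), mu)
  expect_error(cohort_means(m, sheet, "thorax", "young"), "no samples")
})

test_that("fold changes are linear mean ratios with reciprocal symmetry", {
  sheet <- head_sheet(3)
  m <- make_matrix(matrix(c(rep(10, 3), rep(30, 3), rep(30, 3),
                            rep(5, 3), rep(5, 3), rep(5, 3)),
                          nrow = 2, byrow = TRUE),
                   genes = c("a", "b"), samples = sheet$sample_id)
  c_age <- contrast_design("age", "aged", "young", "head")
  fc <- fold_change_contrast(m, sheet, c_age)
  expect_equal(unname(fc), c(3.0, 1.0))
  inv <- fold_change_contrast(m, sheet, contrast_design("rev", "young", "aged", "head"))
  expect_equal(unname(inv), 1 / unname(fc))
  # geometric method agrees on constant replicates
  expect_equal(fold_change_contrast(m, sheet, c_age, method = "geometric"), fc)
})

test_that("Welch test matches stats::t.test gene-wise and handles degenerate input", {
  sheet <- head_sheet(3)
  set.seed(31)
  m <- make_matrix(matrix(rlnorm(10 * 9, 3, 0.7), nrow = 10),
                   samples = sheet$sample_id)
  c_age <- contrast_design("age", "aged", "young", "head")
  p <- differential_test(m, sheet, c_age)
  lm2 <- log2_matrix(m, 0)
  young <- sheet$sample_id[sheet$cohort == "young"]
  aged <- sheet$sample_id[sheet$cohort == "aged"]
  oracle <- apply(lm2, 1, function(r)
    t.test(r[aged], r[young], var.equal = FALSE)$p.value)
  expect_equal(unname(p), unname(oracle), tolerance = 1e-12)

  # identical multisets -> p = 1
  eq <- make_matrix(matrix(rep(c(1, 2, 3), 3), nrow = 1), genes = "a",
                    samples = sheet$sample_id)
  expect_equal(unname(differential_test(eq, sheet, c_age)), 1)

  # clearly separated groups -> p < 0.01
  sep <- make_matrix(matrix(c(1.0, 1.1, 0.9, 4.0, 4.2, 3.8, 1, 1, 1), nrow = 1),
                     genes = "a", samples = sheet$sample_id)
  expect_lt(unname(differential_test(sep, sheet, c_age)), 0.01)

  # a single-replicate cohort yields NA with a warning
  mini <- sheet[sheet$replicate == 1 | sheet$cohort == "young", ]
  expect_warning(p1 <- differential_test(m[, mini$sample_id], mini, c_age),
                 "single replicate")
  expect_true(all(is.na(p1)))
})

test_that("classification applies strict symmetric cutoffs with the aged/treated convention", {
  cfg <- analysis_config()
  rec <- data.frame(
    gene = c("none", "boundary_age", "boundary_if", "youth_down", "youth_up",
             "age_only", "if_only"),
    fc_age = c(1.0, 1.4, 2.0, 0.5, 1.8, 1.5, 1.05),
    fc_if = c(1.0, 2.0, 1.3, 0.7, 1.4, 1.0, 0.6))
  got <- classify_genes(rec, cfg)
  expect_false(got$age_up[got$gene == "boundary_age"])   # 1.4 exactly: strict >
  expect_false(got$if_down[got$gene == "boundary_if"])   # 1.3 exactly: strict >
  # fc_age = 0.5 (down), fc_if = 0.7 < 1/1.3 (treated exceeds aged): youthful
  expect_true(got$age_down[got$gene == "youth_down"])
  expect_true(got$if_up[got$gene == "youth_down"])
  expect_true(got$youthful[got$gene == "youth_down"])
  # fc_age = 1.8 (up), fc_if = 1.4 > 1.3 (treated below aged): youthful
  expect_true(got$youthful[got$gene == "youth_up"])
  expect_false(got$youthful[got$gene == "age_only"])
  expect_false(got$youthful[got$gene == "if_only"])
  # partition invariants
  expect_false(any(got$age_up & got$age_down))
  expect_false(any(got$if_up & got$if_down))
  expect_equal(got$youthful,
               (got$age_down & got$if_up) | (got$age_up & got$if_down))
  expect_error(classify_genes(transform(rec, fc_age = -fc_age), cfg), "positive")
})

test_that("category counts match a brute-force tally and their arithmetic identities", {
  set.seed(41)
  for (i in 1:10) {
    rec <- data.frame(gene = sprintf("g%d", 1:500),
                      fc_age = rlnorm(500, 0, 0.5),
                      fc_if = rlnorm(500, 0, 0.4))
    cfg <- analysis_config()
    got <- classify_genes(rec, cfg)
    counts <- summarize_categories(got, cfg)
    brute_up <- sum(rec$fc_age > 1.4)
    brute_down <- sum(rec$fc_age < 1 / 1.4)
    expect_equal(counts$age_up, brute_up)
    expect_equal(counts$age_down, brute_down)
    expect_equal(counts$change_with_age, counts$age_up + counts$age_down)
    expect_equal(counts$if_more_youthful,
                 counts$age_down_if_up + counts$age_up_if_down)
  }
  # the published head-row structure: 178 + 43 = 221 youthful genes
  flags <- data.frame(
    age_up = rep(c(FALSE, TRUE), c(178, 43)),
    age_down = rep(c(TRUE, FALSE), c(178, 43)),
    if_up = rep(c(TRUE, FALSE), c(178, 43)),
    if_down = rep(c(FALSE, TRUE), c(178, 43)))
  flags$youthful <- (flags$age_down & flags$if_up) | (flags$age_up & flags$if_down)
  expect_equal(summarize_categories(flags)$if_more_youthful, 221)
  expect_equal(summarize_categories(flags)$age_down_if_up, 178)
  expect_equal(summarize_categories(flags)$age_up_if_down, 43)
})

test_that("fold changes, p-values and categories are invariant to global scaling", {
  d <- random_dataset(n = 30, seed = 51)
  cfg <- analysis_config()
  base <- fold_change_table(d$matrix, d$samples, "head", cfg)
  for (c0 in c(0.01, 7, 1e4)) {
    scaled <- fold_change_table(d$matrix * c0, d$samples, "head", cfg)
    expect_equal(scaled$fc_age, base$fc_age, tolerance = 1e-12)
    expect_equal(scaled$fc_if, base$fc_if, tolerance = 1e-12)
    expect_equal(scaled$p_age, base$p_age, tolerance = 1e-9)
    expect_identical(scaled$youthful, base$youthful)
  }
})
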