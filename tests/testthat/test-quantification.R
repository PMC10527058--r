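test_that("total-count normalization equalizes sample depth", {
  counts <- cbind(S1 = c(60, 40), S2 = c(120, 80))
  norm <- normalize_counts(counts, "total_count")
  # totals 100 and 200 -> scale factors 1.5 and 0.75
  expect_equal(norm[, "S1"], counts[, "S1"] * 1.5)
  expect_equal(norm[, "S2"], counts[, "S2"] * 0.75)
  expect_equal(colSums(norm), c(S1 = 150, S2 = 150))

  expect_equal(normalize_counts(counts, "none"), counts)
  equal <- cbind(S1 = c(50, 50), S2 = c(30, 70))
  expect_equal(normalize_counts(equal, "total_count"), equal)
  expect_error(normalize_counts(cbind(S1 = c(0, 0)), "total_count"), "zero")
})

test_that("outlier screen flags a variance-inflated protein and only it", {
  set.seed(5)
  n <- 60
  lam <- exp(rnorm(n, 3, 0.8))
  counts <- t(vapply(lam, function(l) rpois(8, l), numeric(8)))
  # one protein with SD inflated ~100x relative to the Poisson trend
  counts[1, ] <- round(pmax(mean(counts[1, ]) +
                              c(-1, 1) * 50 * sqrt(mean(counts[1, ])), 0))
  rownames(counts) <- sprintf("G%02d", seq_len(n))
  colnames(counts) <- sprintf("S%d", 1:8)
  ol <- exclude_outliers(counts, specuniq_config())
  expect_true(ol$outlier[1])
  expect_lt(sum(ol$outlier), 4)   # the trend itself is not flagged

  # identical proteins: zero residuals, nothing flagged
  flat <- matrix(5, 12, 8, dimnames = list(sprintf("G%d", 1:12),
                                           sprintf("S%d", 1:8)))
  expect_false(any(exclude_outliers(flat, specuniq_config())$outlier))

  # infinite threshold flags nothing
  expect_false(any(exclude_outliers(counts,
    specuniq_config(outlier_sd = Inf))$outlier))

  expect_warning(exclude_outliers(counts[1:5, ], specuniq_config()),
                 "fewer than 10")
})

test_that("fold changes implement the infinite-fold semantics", {
  samples <- table1_samples()
  counts <- rbind(
    UP = c(2, 2, 2, 2, 5, 5, 5, 5),     # FC 2.5, up-regulated
    INF = c(0, 0, 0, 0, 3, 3, 3, 3),    # infinite fold
    FLAT = c(4, 4, 4, 4, 4, 4, 4, 4),   # FC 1
    GONE = c(0, 0, 0, 0, 0, 0, 0, 0))   # undefined, excluded
  colnames(counts) <- samples$sample_id
  fc <- fold_changes(counts, samples, specuniq_config())
  expect_equal(fc$fold_change[1], 2.5)
  expect_true(fc$upregulated[1])
  expect_true(is.infinite(fc$fold_change[2]))
  expect_true(fc$infinite_fold[2])
  expect_false(fc$upregulated[2])   # infinite fold is tracked, not counted
  expect_equal(fc$fold_change[3], 1)
  expect_false(fc$upregulated[3])
  expect_true(is.nan(fc$fold_change[4]))
})

test_that("raising the fold threshold never enlarges the up-regulated set", {
  set.seed(6)
  samples <- table1_samples()
  counts <- matrix(rpois(50 * 8, 20), 50, 8,
                   dimnames = list(sprintf("G%d", 1:50), samples$sample_id))
  up15 <- fold_changes(counts, samples,
                       specuniq_config(fold_change_min = 1.5))$upregulated
  up17 <- fold_changes(counts, samples, specuniq_config())$upregulated
  up25 <- fold_changes(counts, samples,
                       specuniq_config(fold_change_min = 2.5))$upregulated
  expect_true(all(up17 <= up15))
  expect_true(all(up25 <= up17))
})

test_that("fold change is scale-invariant without normalization", {
  samples <- table1_samples()
  counts <- matrix(rpois(20 * 8, 30), 20, 8,
                   dimnames = list(sprintf("G%d", 1:20), samples$sample_id))
  f1 <- fold_changes(counts, samples, specuniq_config())$fold_change
  f2 <- fold_changes(counts * 7, samples, specuniq_config())$fold_change
  expect_equal(f1, f2)
})

test_that("the ANOVA gate detects a planted 8-fold shift with high power", {
  samples <- table1_samples()
  set.seed(7)
  hits <- 0L
  n_rep <- 200L
  for (i in seq_len(n_rep)) {
    counts <- matrix(c(rpois(4, 30), rpois(4, 240)), 1, 8,
                     dimnames = list("G1", samples$sample_id))
    g <- significance_gate(counts, samples, "two_way_anova",
                           specuniq_config())
    if (g$p_gate < 0.01) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("identical group distributions are not called significant", {
  samples <- table1_samples()
  counts <- matrix(rep(c(10, 20, 30, 40), 2), 1, 8,
                   dimnames = list("G1", samples$sample_id))
  g <- significance_gate(counts, samples, "two_way_anova",
                         specuniq_config())
  expect_gte(g$p_gate, 0.5)
  gw <- significance_gate(counts, samples, "welch_log", specuniq_config())
  expect_gte(gw$p_gate, 0.5)
})

test_that("the welch_log gate agrees exactly with the cohort Welch test", {
  samples <- table1_samples()
  counts <- matrix(samples$bmi, 1, 8,
                   dimnames = list("G1", samples$sample_id))
  g <- significance_gate(counts, samples, "welch_log", specuniq_config())
  # same comparison through the cohort-statistics route, on the
  # identically transformed values
  sheet <- samples
  sheet$bmi <- log10(samples$bmi + 0.5)
  expect_equal(g$p_gate, welch_t(sheet, "bmi")$p, tolerance = 1e-12)
})

test_that("zero-variance groups use the variance floor and are flagged", {
  samples <- table1_samples()
  counts <- matrix(c(rep(5, 4), 50, 50, 50, 50), 1, 8,
                   dimnames = list("G1", samples$sample_id))
  g <- significance_gate(counts, samples, "welch_log", specuniq_config())
  expect_true(g$variance_floored)
  # expected p from the floored Welch formula computed independently
  eps <- 0.5
  d <- log10(50 + eps) - log10(5 + eps)
  se2 <- eps^2 / 4 + eps^2 / 4
  tt <- d / sqrt(se2)
  df <- se2^2 / (2 * (eps^2 / 4)^2 / 3)
  expect_equal(g$p_gate, 2 * pt(-tt, df), tolerance = 1e-12)
})
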