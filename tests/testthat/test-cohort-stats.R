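test_that("pooled percentile uses linear interpolation between order stats", {
  expect_equal(pooled_percentile_threshold(list(1:50, 51:100), "upper", 1), 99.01)
  expect_equal(pooled_percentile_threshold(list(rep(3.3, 40)), "upper", 1), 3.3)
  x <- rnorm(500)
  lo <- pooled_percentile_threshold(list(x), "lower", 1)
  hi <- pooled_percentile_threshold(list(-x), "upper", 1)
  expect_equal(lo, -hi, tolerance = 1e-12)
  expect_error(pooled_percentile_threshold(list(numeric())), "no pooled")
})

test_that("pooled percentile accepts wall scalar fields, optionally area-weighted", {
  f1 <- fx_scalar_field(1:10, areas = rep(1, 10))
  f2 <- fx_scalar_field(91:100, areas = rep(1, 10))
  expect_equal(pooled_percentile_threshold(list(f1, f2), "upper", 10),
               unname(quantile(c(1:10, 91:100), 0.9)))
  # weighting all mass onto the upper half shifts the lower percentile up
  fw <- fx_scalar_field(1:10, areas = c(rep(1e-9, 5), rep(1, 5)))
  expect_gte(pooled_percentile_threshold(list(fw), "lower", 20,
                                         area_weighted = TRUE), 6)
})

test_that("ROC follows the Mann-Whitney identity with the half-tie rule", {
  r <- roc_curve(c(2, 1, 3, 4), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(r$auc, 0.75)
  expect_equal(r$gini, 2 * r$auc - 1)
  perfect <- roc_curve(c(5, 6, 7, 1, 2), c(1, 1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$gini, 1)
  tied <- roc_curve(rep(4, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(tied$auc, 0.5)
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "degenerate")
})

test_that("curve AUC equals Mann-Whitney AUC and matches pROC", {
  set.seed(11)
  for (k in 1:10) {
    n <- 30
    scores <- round(rnorm(n), 1)  # rounding forces ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    r <- roc_curve(scores, labels)
    expect_equal(auc_trapezoid(r), r$auc, tolerance = 1e-12)
    expect_true(all(diff(r$curve$fpr) >= 0), info = "FPR non-decreasing")
    expect_true(all(diff(r$curve$tpr) >= 0), info = "TPR non-decreasing")
    expect_equal(r$curve$fpr[c(1, nrow(r$curve))], c(0, 1))
    if (requireNamespace("pROC", quietly = TRUE)) {
      ref <- suppressMessages(pROC::auc(pROC::roc(
        response = labels, predictor = scores, quiet = TRUE,
        direction = "<", levels = c(FALSE, TRUE))))
      expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
    }
  }
})

test_that("threshold sweep picks the max-AUC candidate, smallest on ties", {
  scores <- cbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(1, 3, 2, 4))
  labels <- c(0, 0, 1, 1)
  sw <- threshold_sweep(scores, labels, candidates = c(1, 2, 3))
  expect_equal(sw$best_threshold, 1)  # column a separates perfectly
  expect_equal(sw$best_auc, 1)
  # invariant to candidate ordering
  sw2 <- threshold_sweep(scores[, c(3, 1, 2)], labels, candidates = c(3, 1, 2))
  expect_equal(sw2$best_threshold, sw$best_threshold)
  # all-tied AUCs: smallest candidate wins
  tiedtab <- cbind(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4))
  swt <- threshold_sweep(tiedtab, labels, candidates = c(7, 2))
  expect_equal(swt$best_threshold, 2)
  one <- threshold_sweep(scores[, 1, drop = FALSE], labels, candidates = 5)
  expect_equal(one$best_threshold, 5)
})

test_that("Kruskal-Wallis H and p match the hand formula and kruskal.test", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  kw <- kruskal_wallis_pairwise(g)
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$p_value, stats::kruskal.test(g)$p.value, tolerance = 1e-12)
  ident <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  kw0 <- kruskal_wallis_pairwise(ident)
  expect_equal(kw0$H, 0, tolerance = 1e-12)
  expect_equal(kw0$p_value, 1, tolerance = 1e-12)
  expect_error(kruskal_wallis_pairwise(list(a = 1, b = c(2, 3))), "at least 2")
})

test_that("Dunn z for two groups squares to the tie-corrected H", {
  set.seed(3)
  x <- list(a = round(rnorm(9), 1), b = round(rnorm(7) + 0.8, 1))
  kw <- kruskal_wallis_pairwise(x)
  expect_equal(kw$pairwise$z^2, kw$H, tolerance = 1e-9)
  # Bonferroni multiplies the pairwise p by the number of pairs
  g3 <- list(a = rnorm(5), b = rnorm(5), c = rnorm(5))
  raw <- kruskal_wallis_pairwise(g3, adjust = "none")
  adj <- kruskal_wallis_pairwise(g3, adjust = "bonferroni")
  expect_equal(adj$pairwise$p, pmin(1, raw$pairwise$p * 3), tolerance = 1e-12)
})

test_that("omnibus chi-square p tracks a permutation oracle at moderate n", {
  set.seed(21)
  g <- list(a = rnorm(8), b = rnorm(8) + 0.9, c = rnorm(8) + 0.3)
  kw <- kruskal_wallis_pairwise(g)
  pooled <- unlist(g, use.names = FALSE)
  sizes <- lengths(g)
  idx <- rep(seq_along(g), sizes)
  Hperm <- replicate(4000, {
    stats::kruskal.test(split(pooled, sample(idx)))$statistic
  })
  p_perm <- mean(Hperm >= kw$H - 1e-12)
  # chi-square approximation agrees within Monte-Carlo + approximation slack
  expect_lt(abs(p_perm - kw$p_value), 0.02 + 0.3 * kw$p_value)
})

test_that("group summary table reports means, tests and full-cycle counts", {
  df <- data.frame(
    group = rep(c("caw", "atherosclerosis", "normal"), c(4, 3, 3)),
    stasis_pct = c(100, 100, 95, 100, 60, 55, 65, 85, 80, 90),
    low_velocity_volume_pct = c(12, 11, 10, 13, 5, 6, 4, 5, 5, 6))
  tb <- group_summary_table(df)
  expect_named(tb, c("stasis_pct", "low_velocity_volume_pct"))
  expect_s3_class(tb$stasis_pct, "group_comparison")
  expect_equal(unname(attr(tb, "full_cycle_stasis")[c("caw", "atherosclerosis", "normal")]),
               c(3, 0, 0))
  expect_equal(tb$stasis_pct$groups$n[tb$stasis_pct$groups$group == "caw"], 4L)
  # single group: summary without tests
  one <- group_summary_table(df[df$group == "caw", ])
  expect_false(inherits(one$stasis_pct, "group_comparison"))
  expect_equal(one$stasis_pct$mean, mean(c(100, 100, 95, 100)))
})
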