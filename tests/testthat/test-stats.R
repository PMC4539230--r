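test_that("midranks average over ties and sum to n(n+1)/2", {
  expect_equal(rank_with_ties(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(rank_with_ties(c(5, 5)), c(1.5, 1.5))
  expect_equal(rank_with_ties(c(1, 2, 2, 3)), c(1, 2.5, 2.5, 4))
  set.seed(1)
  for (i in 1:10) {
    x <- sample(1:5, 12, replace = TRUE)
    expect_equal(sum(rank_with_ties(x)), 12 * 13 / 2)
  }
})

test_that("Wilcoxon Z matches the closed form and the exact enumeration", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$w, 6)
  expect_equal(w$z, -4.5 / sqrt(5.25), tolerance = 1e-9)
  expect_equal(exact_wilcoxon_p(c(1, 2, 3), c(4, 5, 6)), 0.100,
               tolerance = 1e-9)
  # continuity-corrected normal p within 0.05 of exact for small distinct
  # samples (the uncorrected variant can deviate by up to ~0.19 at n = 3)
  set.seed(7)
  for (i in 1:20) {
    n_a <- sample(3:6, 1)
    n_b <- sample(3:6, 1)
    vals <- sample(1:50, n_a + n_b)
    a <- vals[seq_len(n_a)]
    b <- vals[-seq_len(n_a)]
    wt <- wilcoxon_rank_sum(a, b, continuity = TRUE)
    expect_lt(abs(wt$p_two_sided - exact_wilcoxon_p(a, b)), 0.05)
  }
})

test_that("Wilcoxon handles ties, degenerate input and group swaps", {
  # identical groups elementwise: perfect symmetry
  w0 <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$z, 0)
  expect_equal(w0$p_two_sided, 1)
  # all values identical: defined result with warning
  expect_warning(wd <- wilcoxon_rank_sum(rep(2, 4), rep(2, 5)), "identical")
  expect_equal(wd$z, 0)
  expect_equal(wd$p_two_sided, 1)
  # swapping group order negates z and mean_rank_diff, p unchanged
  set.seed(3)
  a <- sample(1:8, 10, replace = TRUE)
  b <- sample(2:9, 12, replace = TRUE)
  w1 <- wilcoxon_rank_sum(a, b)
  w2 <- wilcoxon_rank_sum(b, a)
  expect_equal(w1$z, -w2$z)
  expect_equal(w1$mean_rank_diff, -w2$mean_rank_diff)
  expect_equal(w1$p_two_sided, w2$p_two_sided)
  # tie-corrected p agrees with the standard uncorrected normal test
  ref <- stats::wilcox.test(a, b, correct = FALSE, exact = FALSE)
  expect_equal(w1$p_two_sided, ref$p.value, tolerance = 1e-10)
})

test_that("Spearman rho equals rank-Pearson and the no-ties closed form", {
  expect_equal(spearman_corr(1:6, c(2, 4, 9, 11, 30, 31))$rho, 1)
  expect_equal(spearman_corr(1:6, rev(1:6))$rho, -1)
  expect_equal(spearman_corr(c(1, 2, 3, 4), c(1, 3, 2, 4))$rho, 0.8)
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(15)
    y <- rnorm(15)
    s <- spearman_corr(x, y)
    expect_equal(s$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
    d <- rank(x) - rank(y)
    expect_equal(s$rho, 1 - 6 * sum(d^2) / (15 * (15^2 - 1)),
                 tolerance = 1e-12)
    ref <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(s$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(s$p_two_sided, ref$p.value, tolerance = 1e-9)
  }
  # zero rank variance flags a degenerate result
  dg <- spearman_corr(rep(1, 5), 1:5)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$rho))
})

test_that("correlation-difference statistic is antisymmetric", {
  expect_equal(corr_diff_statistic(1:5, c(2, 3, 5, 7, 11),
                                   1:5, c(2, 3, 5, 7, 11)), 0)
  expect_equal(corr_diff_statistic(1:4, 1:4, 1:4, 4:1), 2)
  set.seed(5)
  xa <- rnorm(8); ya <- rnorm(8); xb <- rnorm(9); yb <- rnorm(9)
  expect_equal(corr_diff_statistic(xa, ya, xb, yb),
               -corr_diff_statistic(xb, yb, xa, ya))
})

test_that("permutation test is deterministic, symmetric and exact for identical groups", {
  xa <- c(1, 2, 3, 5); ya <- c(2, 1, 4, 5)
  # identical pair sets: observed diff 0, every null |diff| >= 0
  r0 <- permutation_corr_diff(xa, ya, xa, ya, n_resamples = 500, seed = 2)
  expect_equal(r0$observed_diff, 0)
  expect_equal(r0$p_two_sided, 1)
  # same seed, same inputs: identical results
  xb <- c(2, 3, 4, 6); yb <- c(6, 4, 3, 1)
  r1 <- permutation_corr_diff(xa, ya, xb, yb, n_resamples = 2000, seed = 9)
  r2 <- permutation_corr_diff(xa, ya, xb, yb, n_resamples = 2000, seed = 9)
  expect_identical(r1$p_two_sided, r2$p_two_sided)
  expect_equal(r1$seed, 9L)
  # two-sided p invariant under group swap (up to Monte-Carlo error;
  # the exhaustive path checks exact invariance)
  r3 <- permutation_corr_diff(xb, yb, xa, ya, n_resamples = 2000, seed = 9)
  expect_equal(r3$observed_diff, -r1$observed_diff)
  expect_lt(abs(r3$p_two_sided - r1$p_two_sided), 0.03)
  e1 <- exhaustive_corr_diff_null(xa, ya, xb, yb)
  e2 <- exhaustive_corr_diff_null(xb, yb, xa, ya)
  expect_identical(e1$p_two_sided, e2$p_two_sided)
})

test_that("Monte-Carlo p converges to the exhaustive relabeling oracle", {
  set.seed(21)
  xa <- rnorm(3); ya <- xa + rnorm(3, sd = 0.2)      # concordant
  xb <- rnorm(3); yb <- -xb + rnorm(3, sd = 0.2)     # discordant
  ex <- exhaustive_corr_diff_null(xa, ya, xb, yb)
  expect_equal(ex$n_resamples, choose(6, 3))
  mc <- permutation_corr_diff(xa, ya, xb, yb, n_resamples = 100000,
                              seed = 4)
  expect_lt(abs(mc$p_two_sided - ex$p_two_sided), 0.01)
  # exhaustive path has no randomness: identical across calls
  ex2 <- exhaustive_corr_diff_null(xa, ya, xb, yb)
  expect_identical(ex$p_two_sided, ex2$p_two_sided)
})

test_that("exhaustive null matches an independent enumeration", {
  xa <- c(1, 2, 3); ya <- c(10, 20, 30)
  xb <- c(4, 5, 6); yb <- c(60, 50, 40)
  ex <- exhaustive_corr_diff_null(xa, ya, xb, yb)
  expect_equal(ex$observed_diff, 2)
  # independent oracle: base-R Spearman over every labeling
  x <- c(xa, xb); y <- c(ya, yb)
  combs <- utils::combn(6, 3)
  diffs <- apply(combs, 2, function(ia) {
    ib <- setdiff(1:6, ia)
    suppressWarnings(cor(x[ia], y[ia], method = "spearman") -
                       cor(x[ib], y[ib], method = "spearman"))
  })
  expect_equal(ex$p_two_sided, mean(abs(diffs) >= 2 - 1e-12))
  # identical groups: p = 1 exactly
  exi <- exhaustive_corr_diff_null(xa, ya, xa, ya)
  expect_equal(exi$p_two_sided, 1)
  expect_error(exhaustive_corr_diff_null(rnorm(15), rnorm(15),
                                         rnorm(15), rnorm(15)),
               "exceeds")
})

test_that("median and quartiles follow the interpolation convention", {
  expect_equal(median_iqr(c(1, 2, 3, 4, 5)),
               c(median = 3, q1 = 2, q3 = 4))
  expect_equal(median_iqr(7), c(median = 7, q1 = 7, q3 = 7))
  expect_equal(median_iqr(1:4), c(median = 2.5, q1 = 1.75, q3 = 3.25))
})

test_that("tidiers return one-row tibbles mirroring the result fields", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  tw <- tidy(w)
  expect_s3_class(tw, "tbl_df")
  expect_equal(tw$z, w$z)
  s <- spearman_corr(1:5, c(2, 1, 4, 3, 5))
  expect_equal(tidy(s)$rho, s$rho)
  p <- permutation_corr_diff(1:4, c(2, 1, 4, 3), 1:4, c(4, 3, 1, 2),
                             n_resamples = 200, seed = 1)
  tp <- tidy(p)
  expect_equal(tp$p_two_sided, p$p_two_sided)
  expect_false(tp$exhaustive)
})
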