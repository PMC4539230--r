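test_that("delay normalization scales by the maximum delay", {
  expect_equal(normalize_delays(c(0, 1080, 2160)), c(0, 0.5, 1))
  sdt <- normalize_delays(sdt_schedule()$delay_hours)
  expect_equal(sdt[1], 0)
  expect_equal(sdt[length(sdt)], 1)
  ddt <- normalize_delays(ddt_schedule()$delay_hours)
  expect_equal(ddt[1], 24 / 43800)
  expect_error(normalize_delays(numeric(0)), "empty")
  expect_error(normalize_delays(c(3, 2, 1)), "increasing")
  expect_error(normalize_delays(c(-1, 5)), "non-negative")
})

test_that("VAS conversion maps 0-100 to proportions and polices range", {
  expect_equal(vas_to_proportion(c(0, 37, 100)), c(0, 0.37, 1))
  expect_error(vas_to_proportion(101), "outside")
  expect_warning(out <- vas_to_proportion(c(-3, 105), mode = "lenient"),
                 "clipped 2")
  expect_equal(out, c(0, 1))
})

test_that("trapezoidal AUC reproduces closed-form cases", {
  delays <- sdt_schedule()$delay_hours
  # constant curves integrate to the constant
  for (const in c(0, 0.25, 0.5, 0.9, 1)) {
    res <- compute_auc(make_curve(rep(const, 8)))
    expect_equal(res$auc, const)
  }
  # hand trapezoid: flat 1 until 1 month, 0 at 3 months
  res <- compute_auc(make_curve(c(1, 1, 1, 1, 1, 1, 1, 0)))
  expect_equal(res$auc, 2 / 3, tolerance = 1e-9)
})

test_that("AUC is bounded, monotone in each value, and matches the Riemann oracle", {
  delays <- sdt_schedule()$delay_hours
  set.seed(42)
  for (i in 1:25) {
    v <- runif(8)
    auc <- compute_auc(make_curve(v))$auc
    expect_gte(auc, 0)
    expect_lte(auc, 1)
    expect_equal(auc, riemann_auc(delays, v), tolerance = 1e-9)
    # raising one value never decreases the AUC
    j <- sample(8, 1)
    v2 <- v
    v2[j] <- min(1, v[j] + runif(1, 0, 1 - v[j]))
    expect_gte(compute_auc(make_curve(v2))$auc, auc - 1e-12)
  }
})

test_that("monetary curves get the undelayed anchor before integration", {
  delays <- ddt_schedule()$delay_hours
  v <- c(0.95, 0.9, 0.7, 0.5, 0.3, 0.1)
  res <- compute_auc(make_curve(v, condition = "monetary",
                                commodity = "monetary", delays = delays))
  expect_equal(res$auc, riemann_auc(c(0, delays), c(1, v)), tolerance = 1e-9)
  # constant-1 monetary curve has AUC 1
  res1 <- compute_auc(make_curve(rep(1, 6), condition = "monetary",
                                 commodity = "monetary", delays = delays))
  expect_equal(res1$auc, 1)
})

test_that("the zero-delay SDT trial can be excluded from the AUC", {
  v <- c(0.2, 1, 1, 1, 1, 1, 1, 1)  # aberrant zero-delay response
  measured <- compute_auc(make_curve(v))$auc
  excluded <- compute_auc(make_curve(v), auc_anchor = "exclude-zero")$auc
  expect_lt(measured, excluded)
  expect_equal(excluded, 1)
})

test_that("curves with missing responses are excluded and counted", {
  curves <- dplyr::bind_rows(
    make_curve(c(1, 1, 1, 1, 1, 1, 1, NA), id = "p1"),
    make_curve(rep(0.5, 8), id = "p2")
  )
  res <- compute_auc(curves)
  expect_equal(nrow(res), 1)
  expect_equal(res$participant_id, "p2")
  expect_equal(attr(res, "n_excluded"), 1)
  expect_error(compute_auc(curves, na_action = "error"), "missing")
})

test_that("monetary consistency criteria flag rising and flat curves", {
  expect_true(check_ddt_consistency(c(0.95, 0.9, 0.7, 0.5, 0.3, 0.1))$pass)
  rising <- check_ddt_consistency(c(0.5, 0.8, 0.7, 0.5, 0.3, 0.1))
  expect_false(rising$pass)
  expect_match(rising$reasons, "0.20", all = FALSE)
  flat <- check_ddt_consistency(rep(0.5, 6))
  expect_false(flat$pass)
  expect_match(flat$reasons, "0.10", all = FALSE)
  expect_error(check_ddt_consistency(rep(0.5, 5)), "6 indifference")
})

test_that("curve tables round-trip through CSV", {
  curves <- dplyr::bind_rows(
    make_curve(runif(8), id = "a"),
    make_curve(runif(6), id = "a", condition = "monetary",
               commodity = "monetary", delays = ddt_schedule()$delay_hours)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_curves(curves, path)
  back <- read_curves(path)
  expect_equal(as.data.frame(back), as.data.frame(curves))
})
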