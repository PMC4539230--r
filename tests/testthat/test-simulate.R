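test_that("hyperbolic response follows the closed form without noise", {
  # k = 1/720 per hour halves the value at 720 h
  v <- simulate_sdt_response(1 / 720, "regular",
                             delay_hours = c(0, 720), sigma_vas = 0)
  expect_equal(v, c(100, 50))
  # vanishing k: no discounting anywhere
  v0 <- simulate_sdt_response(1e-12, "regular", sigma_vas = 0)
  expect_equal(v0, rep(100, 8), tolerance = 1e-6)
  # huge k: immediate preference beyond the zero-delay trial
  v1 <- simulate_sdt_response(1e6, "regular", sigma_vas = 0)
  expect_equal(v1[1], 100)
  expect_true(all(v1[-1] < 0.1))
  # extreme responder types pin the whole curve
  expect_equal(simulate_sdt_response(0.01, "floor"), rep(0, 8))
  expect_equal(simulate_sdt_response(0.01, "ceiling"), rep(100, 8))
})

test_that("titration ladder brackets the true indifference value", {
  # patient agent climbs to the ladder top (~998 of 1000)
  expect_equal(simulate_ddt_titration(0, 24) * 1000, 998.046875)
  # extremely impulsive agent falls to the ladder bottom (~2 of 1000)
  expect_equal(simulate_ddt_titration(100, 24) * 1000, 1.953125)
  # deterministic error bound: within the final step of 1000/(1+kD)
  final_step <- 250 / 2^7
  set.seed(8)
  for (i in 1:30) {
    k <- exp(runif(1, -12, 0))
    d <- sample(ddt_schedule()$delay_hours, 1)
    v_true <- 1000 / (1 + k * d)
    got <- simulate_ddt_titration(k, d) * 1000
    if (v_true > 2 && v_true < 998) {
      expect_lte(abs(got - v_true), final_step + 1e-9)
    }
  }
})

test_that("degenerate mixture and spread settings behave as configured", {
  cfg_floor <- sim_config(n_per_scenario = c(positive = 15, negative = 15,
                                             negative_regret = 15),
                          p_floor = 1, p_ceiling = 0, seed = 1)
  coh <- generate_cohort(cfg_floor)
  auc <- cohort_auc(coh)
  expect_true(all(auc$auc[auc$condition != "monetary"] == 0))

  cfg_flat <- sim_config(n_per_scenario = c(positive = 10, negative = 10,
                                            negative_regret = 10),
                         sigma_log_k = 0, cond_noise_w = 0,
                         p_floor = 0, p_ceiling = 0, gender_effect = 0,
                         scenario_effects = "none", seed = 2)
  agents <- withr::with_seed(3, sample_agents(cfg_flat, "positive", 50))
  expect_equal(length(unique(agents$k_most_attractive)), 1)
})

test_that("AUC is strictly decreasing in k without noise or mixture", {
  ks <- 10^seq(-5, 0, length.out = 12)
  aucs <- vapply(ks, function(k) {
    vas <- simulate_sdt_response(k, "regular", sigma_vas = 0)
    compute_auc(make_curve(vas / 100))$auc
  }, numeric(1))
  expect_true(all(diff(aucs) < 0))
})

test_that("mixture weights calibrate the AUC point masses", {
  cfg <- sim_config(n_per_scenario = c(positive = 1700, negative = 1700,
                                       negative_regret = 1600),
                    seed = 31)
  coh <- generate_cohort(cfg)
  auc <- cohort_auc(coh)
  for (cond in sdt_conditions()) {
    a <- auc$auc[auc$condition == cond]
    # binomial SE at n = 5000 is about 0.005; allow 4 SE
    expect_lt(abs(mean(a == 0) - cfg$p_floor), 0.02)
    expect_lt(abs(mean(a == 1) - cfg$p_ceiling), 0.02)
  }
})

test_that("cohort generation is reproducible from the seed", {
  cfg <- sim_config(n_per_scenario = c(positive = 2, negative = 2,
                                       negative_regret = 2), seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, p1, config = cfg)
  write_cohort(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_true(file.exists(paste0(p1, ".json")))
  side <- jsonlite::read_json(paste0(p1, ".json"))
  expect_equal(side$seed, 99)
})

test_that("cohort has the documented structure", {
  coh <- make_test_cohort(seed = 6)
  expect_equal(nrow(coh), 60)
  expect_true(all(coh$image_count >= 2))
  expect_true(all(coh$scenario %in% scenario_levels()))
  expect_true(all(coh$hrbs_score >= 0 & coh$hrbs_score <= 55))
  expect_true(all(coh$ztpi_score >= 1 & coh$ztpi_score <= 5))
  expect_true(all(coh$sss_score >= 21 & coh$sss_score <= 105))
  sdt_cols <- paste0("most_attractive_h", sdt_schedule()$delay_hours)
  mon_cols <- paste0("monetary_h", ddt_schedule()$delay_hours)
  expect_true(all(c(sdt_cols, mon_cols) %in% names(coh)))
})

test_that("zero copula targets yield uncorrelated traits", {
  cfg <- sim_config(n_per_scenario = c(positive = 1700, negative = 1700,
                                       negative_regret = 1600),
                    copula_targets = c(monetary_auc = 0, ztpi = 0,
                                       image_count = 0, hrbs = 0,
                                       sss = 0, cfc = 0),
                    seed = 13)
  coh <- generate_cohort(cfg)
  auc <- cohort_auc(coh)
  t3 <- table3_analysis(coh, auc = auc)
  expect_true(all(abs(t3$rho) < 0.05))
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(sim_config(p_floor = 0.7, p_ceiling = 0.5), "mixture")
  expect_error(sim_config(copula_targets = c(monetary_auc = 1.2, ztpi = 0,
                                             image_count = 0, hrbs = 0,
                                             sss = 0, cfc = 0)),
               "monetary_auc")
})
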