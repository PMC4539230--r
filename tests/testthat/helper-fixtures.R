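# shared fixtures: tiny cohorts and foreign-layout files built in code

make_test_cohort <- function(n = c(positive = 20, negative = 20,
                                   negative_regret = 20),
                             seed = 1, ...) {
  generate_cohort(sim_config(n_per_scenario = n, seed = seed, ...))
}

# one tidy sexual curve
make_curve <- function(values, id = "p1", condition = "most_attractive",
                       commodity = "sexual",
                       delays = sdt_schedule()$delay_hours) {
  tibble::tibble(participant_id = id, commodity = commodity,
                 condition = condition, delay_hours = delays,
                 value = values)
}

# brute-force AUC oracle: fine midpoint Riemann sum over the
# piecewise-linear interpolant on normalized positions, divided by the
# position span (the same normalization compute_auc applies)
riemann_auc <- function(delay_hours, values, n_grid = 2000000) {
  x <- delay_hours / max(delay_hours)
  mids <- (seq_len(n_grid) - 0.5) / n_grid * (max(x) - min(x)) + min(x)
  mean(stats::approx(x, values, xout = mids)$y)
}

# exact two-sided rank-sum p by enumerating every group assignment
exact_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  n_a <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n_a)])
  e <- n_a * (n + 1) / 2
  combs <- utils::combn(n, n_a)
  ws <- apply(combs, 2, function(ix) sum(r[ix]))
  mean(abs(ws - e) >= abs(w_obs - e) - 1e-9)
}

# foreign-layout participant file (synthetic stand-in for a deposited
# dataset): odd column names, VAS stored as proportions, plus
# precomputed AUC columns
write_s1_like_file <- function(path, n = 12, seed = 3) {
  coh <- make_test_cohort(c(positive = n, negative = n,
                            negative_regret = n), seed = seed)
  auc <- cohort_auc(coh)
  wide_auc <- tidyr::pivot_wider(auc, names_from = condition,
                                 values_from = auc, names_prefix = "AUC.")
  out <- tibble::tibble(
    SubjID = coh$participant_id,
    Group = c(positive = "Pos", negative = "NegNoReg",
              negative_regret = "NegReg")[coh$scenario],
    Sex = coh$gender,
    AgeYrs = coh$age,
    HRBS.Total = coh$hrbs_score,
    ZTPI.Mean = coh$ztpi_score,
    SSS.Total = coh$sss_score,
    CFC.Mean = coh$cfc_score,
    NImages = coh$image_count
  )
  out <- dplyr::left_join(
    out,
    dplyr::rename(wide_auc, SubjID = participant_id),
    by = "SubjID")
  readr::write_csv(out, path)
  invisible(coh)
}

s1_like_mapping <- function() {
  column_mapping(
    columns = c(participant_id = "SubjID", scenario = "Group",
                gender = "Sex", age = "AgeYrs", hrbs_score = "HRBS.Total",
                ztpi_score = "ZTPI.Mean", sss_score = "SSS.Total",
                cfc_score = "CFC.Mean", image_count = "NImages"),
    auc_columns = c(least_attractive = "AUC.least_attractive",
                    most_attractive = "AUC.most_attractive",
                    least_sti = "AUC.least_sti",
                    most_sti = "AUC.most_sti",
                    monetary = "AUC.monetary"),
    scenario_levels_map = c(Pos = "positive", NegNoReg = "negative",
                            NegReg = "negative_regret")
  )
}
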