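#' Tidy curve extraction from a participant-level cohort table
#'
#' Converts the wide cohort layout (`<condition>_h<delay>` columns, VAS
#' 0-100 for sexual conditions and dollars out of 1000 for monetary) into
#' the tidy curve table consumed by [compute_auc()], with values as
#' proportions in `[0, 1]`.
#'
#' @param cohort A cohort tibble (see [generate_cohort()]).
#' @param vas_scale Scale of stored sexual responses (100 when stored as
#'   VAS 0-100, 1 when already proportions).
#' @param money_scale Scale of stored monetary indifference points (1000
#'   when stored in dollars, 1 when already proportions).
#' @param vas_mode Passed to [vas_to_proportion()] handling of
#'   out-of-range values.
#' @return A tidy curve tibble: `participant_id`, `commodity`,
#'   `condition`, `delay_hours`, `value`.
#' @export
cohort_curves <- function(cohort, vas_scale = 100, money_scale = 1000,
                          vas_mode = "strict") {
  curve_cols <- grep(paste0("^(", paste(all_conditions(), collapse = "|"),
                            ")_h[0-9]+$"), names(cohort), value = TRUE)
  if (length(curve_cols) == 0) {
    stop("no curve columns of the form <condition>_h<delay> found",
         call. = FALSE)
  }
  long <- cohort |>
    dplyr::select("participant_id", dplyr::all_of(curve_cols)) |>
    tidyr::pivot_longer(-"participant_id", names_to = "key",
                        values_to = "raw") |>
    tidyr::extract("key", into = c("condition", "delay_hours"),
                   regex = "^(.*)_h([0-9]+)$", convert = TRUE) |>
    dplyr::mutate(
      commodity = ifelse(.data$condition == "monetary", "monetary", "sexual"),
      value = dplyr::if_else(
        .data$commodity == "monetary",
        .data$raw / money_scale,
        NA_real_
      )
    ) |>
    (\(d) {
      sexual <- d$commodity == "sexual"
      d$value[sexual] <- vas_to_proportion(d$raw[sexual] * (100 / vas_scale),
                                           mode = vas_mode)
      d
    })() |>
    dplyr::select("participant_id", "commodity", "condition",
                  "delay_hours", "value") |>
    dplyr::arrange(.data$participant_id, .data$condition, .data$delay_hours)
  long
}

#' Per-participant AUC for every condition
#'
#' Computes the trapezoidal AUC for the four sexual partner conditions
#' and the monetary curve. When the cohort carries precomputed
#' `auc_<condition>` columns (deposited datasets that store AUC rather
#' than trial-level responses, loaded through [read_cohort_mapped()]),
#' those are returned directly and the curve stage is bypassed.
#'
#' @inheritParams cohort_curves
#' @param auc_anchor Passed to [compute_auc()].
#' @return A tibble `participant_id`, `condition`, `auc`.
#' @export
cohort_auc <- function(cohort, auc_anchor = "measured", vas_scale = 100,
                       money_scale = 1000, vas_mode = "strict") {
  pre <- grep("^auc_", names(cohort), value = TRUE)
  if (length(pre) > 0) {
    out <- cohort |>
      dplyr::select("participant_id", dplyr::all_of(pre)) |>
      tidyr::pivot_longer(-"participant_id", names_to = "condition",
                          values_to = "auc",
                          names_transform = function(x) sub("^auc_", "", x))
    return(dplyr::arrange(out, .data$participant_id, .data$condition))
  }
  compute_auc(
    cohort_curves(cohort, vas_scale = vas_scale, money_scale = money_scale,
                  vas_mode = vas_mode),
    auc_anchor = auc_anchor
  )
}

#' Column mapping for foreign cohort files
#'
#' Bridges an arbitrary deposited file layout to the canonical cohort
#' schema. `columns` maps canonical names to source column names; fields
#' genuinely absent from the source are declared in `absent` (they are
#' filled with `NA` and downstream analyses that need them flag their
#' rows). `auc_columns` maps conditions to source columns holding
#' precomputed AUC values, bypassing the curve stage. `scenario_levels_map`
#' recodes source scenario labels to the canonical
#' positive/negative/negative_regret levels.
#'
#' @param columns Named character vector or list, canonical -> source.
#' @param auc_columns Optional named vector, condition -> source column.
#' @param vas_scale,money_scale Scale of stored responses in the source.
#' @param scenario_levels_map Optional named vector, source label ->
#'   canonical scenario level.
#' @param absent Character vector of canonical fields declared absent.
#' @return An object of class `"column_mapping"`.
#' @export
column_mapping <- function(columns = c(), auc_columns = NULL,
                           vas_scale = 100, money_scale = 1000,
                           scenario_levels_map = NULL, absent = character()) {
  structure(list(columns = unlist(columns), auc_columns = auc_columns,
                 vas_scale = vas_scale, money_scale = money_scale,
                 scenario_levels_map = scenario_levels_map,
                 absent = absent),
            class = "column_mapping")
}

#' Read a cohort file through a column mapping
#'
#' Reads a delimited participant-level file, renames mapped columns to
#' the canonical schema, recodes scenario labels, attaches precomputed
#' AUC columns as `auc_<condition>` when mapped, and validates the
#' result. Required canonical fields (`participant_id`, `scenario`) must
#' be mapped or already present; a missing mapped source column is an
#' error naming the column.
#'
#' @param path CSV file path.
#' @param mapping A [column_mapping()]; `NULL` reads the canonical layout.
#' @return A cohort tibble with attributes `vas_scale` and `money_scale`.
#' @export
read_cohort_mapped <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_guess()), show_col_types = FALSE)
  if (is.null(mapping)) mapping <- column_mapping()
  cols <- mapping$columns
  if (length(cols) > 0) {
    missing_src <- setdiff(unname(cols), names(raw))
    if (length(missing_src) > 0) {
      stop("mapped source column(s) not in file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    for (canon in names(cols)) names(raw)[names(raw) == cols[[canon]]] <- canon
  }
  if (!is.null(mapping$auc_columns)) {
    for (cond in names(mapping$auc_columns)) {
      src <- mapping$auc_columns[[cond]]
      if (!src %in% names(raw)) {
        stop("AUC source column not in file: ", src, call. = FALSE)
      }
      raw[[paste0("auc_", cond)]] <- raw[[src]]
    }
  }
  if (!is.null(mapping$scenario_levels_map) && "scenario" %in% names(raw)) {
    m <- mapping$scenario_levels_map
    raw$scenario <- ifelse(raw$scenario %in% names(m),
                           unname(m[raw$scenario]), raw$scenario)
  }
  for (f in mapping$absent) if (!f %in% names(raw)) raw[[f]] <- NA
  required <- c("participant_id", "scenario")
  missing_req <- setdiff(required, names(raw))
  if (length(missing_req) > 0) {
    stop("required field(s) unmapped and absent: ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  bad <- !raw$scenario %in% scenario_levels() & !is.na(raw$scenario)
  if (any(bad)) {
    stop("unrecognized scenario label(s) in rows: ",
         paste(utils::head(which(bad), 10), collapse = ", "), call. = FALSE)
  }
  raw$participant_id <- as.character(raw$participant_id)
  attr(raw, "vas_scale") <- mapping$vas_scale
  attr(raw, "money_scale") <- mapping$money_scale
  raw
}

#' Render a scenario script for a participant
#'
#' The three scenario scripts (positive outcome, negative outcome,
#' negative outcome with regret expression) are shipped as text templates
#' that differ only in the manipulated spans. The best friend's gender
#' and the participant's age are substituted into the placeholders.
#'
#' @param template_id One of `scenario_levels()`.
#' @param gender `"male"` or `"female"` (the friend's gender).
#' @param age Age in years.
#' @return The rendered scenario text (single string).
#' @export
render_scenario <- function(template_id, gender = c("female", "male"), age) {
  gender <- match.arg(gender)
  if (!template_id %in% scenario_levels()) {
    stop("unknown scenario template: ", template_id, call. = FALSE)
  }
  path <- system.file("extdata", paste0("scenario_", template_id, ".txt"),
                      package = "sexdisc", mustWork = TRUE)
  txt <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
               collapse = "\n")
  she_he <- if (gender == "female") "she" else "he"
  his_her <- if (gender == "female") "her" else "his"
  subs <- c("\\{\\{GENDER\\}\\}" = gender,
            "\\{\\{AGE\\}\\}" = as.character(age),
            "\\{\\{SHE_HE_CAP\\}\\}" = paste0(toupper(substr(she_he, 1, 1)),
                                              substr(she_he, 2, 10)),
            "\\{\\{SHE_HE\\}\\}" = she_he,
            "\\{\\{HIS_HER\\}\\}" = his_her)
  for (pat in names(subs)) txt <- gsub(pat, subs[[pat]], txt)
  txt
}

# scenario pairs in the published table order (group_a, group_b)
scenario_pairs <- function() {
  list(c("negative", "negative_regret"),
       c("positive", "negative"),
       c("positive", "negative_regret"))
}

sig_marks <- function(p, cut1 = 0.05, cut2 = 0.001) {
  dplyr::case_when(is.na(p) ~ "", p < cut2 ~ "**", p < cut1 ~ "*",
                   TRUE ~ "")
}

#' Pairwise Wilcoxon comparisons of AUC between scenarios
#'
#' For each of the four partner conditions and the monetary curve, runs
#' the three pairwise scenario comparisons of the AUC distributions with
#' the tie-corrected Wilcoxon rank-sum Z ([wilcoxon_rank_sum()]), listed
#' in the published order. Z follows the first-listed group's rank sum: a
#' negative Z means the first group's AUC ranks lower (steeper
#' discounting). 15 rows.
#'
#' @param cohort A cohort tibble.
#' @param auc Optional precomputed [cohort_auc()] table.
#' @param ... Passed to [cohort_auc()] when `auc` is not supplied.
#' @return A tibble with columns `condition`, `group_a`, `group_b`,
#'   `n_a`, `n_b`, `mean_rank_diff`, `z`, `p_two_sided`, `sig`, `note`.
#'   Comparisons with an empty group are flagged in `note`, never
#'   dropped.
#' @export
table1_analysis <- function(cohort, auc = NULL, ...) {
  if (is.null(auc)) auc <- cohort_auc(cohort, ...)
  dat <- dplyr::left_join(auc,
                          dplyr::select(cohort, "participant_id", "scenario"),
                          by = "participant_id")
  rows <- list()
  for (cond in all_conditions()) {
    for (pair in scenario_pairs()) {
      sub <- dplyr::filter(dat, .data$condition == cond, !is.na(.data$auc))
      a <- sub$auc[sub$scenario == pair[1]]
      b <- sub$auc[sub$scenario == pair[2]]
      if (length(a) < 2 || length(b) < 2) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          condition = cond, group_a = pair[1], group_b = pair[2],
          n_a = length(a), n_b = length(b), mean_rank_diff = NA_real_,
          z = NA_real_, p_two_sided = NA_real_,
          note = "insufficient observations")
        next
      }
      wt <- suppressWarnings(wilcoxon_rank_sum(a, b))
      rows[[length(rows) + 1]] <- tibble::tibble(
        condition = cond, group_a = pair[1], group_b = pair[2],
        n_a = wt$n_a, n_b = wt$n_b, mean_rank_diff = wt$mean_rank_diff,
        z = wt$z, p_two_sided = wt$p_two_sided, note = "")
    }
  }
  out <- dplyr::bind_rows(rows)
  out$sig <- sig_marks(out$p_two_sided, 0.05, 0.001)
  out
}

#' Permutation comparison of AUC-HRBS correlation strength by scenario
#'
#' For each partner condition and scenario pair, tests whether the
#' Spearman correlation between sexual AUC and HRBS total differs
#' between the two scenario groups, using the label-permutation test
#' ([permutation_corr_diff()]) with `n_resamples` relabelings. 12 rows;
#' every row records its own seed (derived deterministically from
#' `seed`).
#'
#' @inheritParams table1_analysis
#' @param n_resamples Relabelings per row (default 100,000).
#' @param seed Master seed for the resampling.
#' @return A tibble with `condition`, `group_a`, `group_b`, `rho_a`,
#'   `rho_b`, `observed_diff`, `p_two_sided`, `n_resamples`,
#'   `n_degenerate`, `seed`, `sig`, `note`.
#' @export
table2_analysis <- function(cohort, auc = NULL, n_resamples = 100000L,
                            seed = 1L, ...) {
  if (is.null(auc)) auc <- cohort_auc(cohort, ...)
  if (!"hrbs_score" %in% names(cohort)) {
    stop("cohort has no hrbs_score column", call. = FALSE)
  }
  dat <- dplyr::left_join(
    auc, dplyr::select(cohort, "participant_id", "scenario", "hrbs_score"),
    by = "participant_id")
  rows <- list()
  i <- 0L
  for (cond in sdt_conditions()) {
    for (pair in scenario_pairs()) {
      i <- i + 1L
      row_seed <- (as.integer(seed) + 1000L * i) %% .Machine$integer.max
      sub <- dplyr::filter(dat, .data$condition == cond,
                           !is.na(.data$auc), !is.na(.data$hrbs_score))
      # canonical participant order so the resampling stream (and hence
      # the Monte-Carlo p) is invariant to input row order
      sub <- dplyr::arrange(sub, .data$participant_id)
      a <- sub[sub$scenario == pair[1], ]
      b <- sub[sub$scenario == pair[2], ]
      if (nrow(a) < 3 || nrow(b) < 3) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          condition = cond, group_a = pair[1], group_b = pair[2],
          rho_a = NA_real_, rho_b = NA_real_, observed_diff = NA_real_,
          p_two_sided = NA_real_, n_resamples = n_resamples,
          n_degenerate = NA_integer_, seed = row_seed,
          note = "insufficient observations")
        next
      }
      res <- permutation_corr_diff(a$auc, a$hrbs_score, b$auc, b$hrbs_score,
                                   n_resamples = n_resamples,
                                   seed = row_seed)
      rows[[length(rows) + 1]] <- tibble::tibble(
        condition = cond, group_a = pair[1], group_b = pair[2],
        rho_a = res$rho_a, rho_b = res$rho_b,
        observed_diff = res$observed_diff,
        p_two_sided = res$p_two_sided, n_resamples = res$n_resamples,
        n_degenerate = res$n_degenerate, seed = row_seed, note = "")
    }
  }
  out <- dplyr::bind_rows(rows)
  out$sig <- sig_marks(out$p_two_sided, 0.05, 0.01)
  out
}

#' Spearman correlations between sexual AUC and other measures
#'
#' Pooled across scenarios, correlates each partner condition's sexual
#' AUC with monetary AUC, ZTPI future score, image count, HRBS, SSS and
#' CFC totals. 24 rows; a constant measure yields a flagged undefined
#' correlation, never a dropped row.
#'
#' @inheritParams table1_analysis
#' @return A tibble with `condition`, `measure`, `rho`, `p_two_sided`,
#'   `n`, `sig`, `note`.
#' @export
table3_analysis <- function(cohort, auc = NULL, ...) {
  if (is.null(auc)) auc <- cohort_auc(cohort, ...)
  wide <- tidyr::pivot_wider(auc, names_from = "condition",
                             values_from = "auc", names_prefix = "auc_")
  measures <- c(monetary_auc = "auc_monetary", ztpi = "ztpi_score",
                image_count = "image_count", hrbs = "hrbs_score",
                sss = "sss_score", cfc = "cfc_score")
  dat <- dplyr::left_join(wide, cohort, by = "participant_id")
  rows <- list()
  for (cond in sdt_conditions()) {
    x_all <- dat[[paste0("auc_", cond)]]
    for (m in names(measures)) {
      col <- measures[[m]]
      if (!col %in% names(dat)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          condition = cond, measure = m, rho = NA_real_,
          p_two_sided = NA_real_, n = 0L, note = "measure absent")
        next
      }
      y_all <- dat[[col]]
      keep <- !is.na(x_all) & !is.na(y_all)
      if (sum(keep) < 3) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          condition = cond, measure = m, rho = NA_real_,
          p_two_sided = NA_real_, n = sum(keep),
          note = "insufficient observations")
        next
      }
      sc <- spearman_corr(x_all[keep], y_all[keep])
      rows[[length(rows) + 1]] <- tibble::tibble(
        condition = cond, measure = m, rho = sc$rho,
        p_two_sided = sc$p_two_sided, n = sc$n,
        note = if (sc$degenerate) "zero rank variance" else "")
    }
  }
  out <- dplyr::bind_rows(rows)
  out$sig <- sig_marks(out$p_two_sided, 0.05, 0.01)
  out
}

#' Wilcoxon contrast of sexual AUC by gender
#'
#' Pooled across scenarios, compares male versus female AUC in each
#' partner condition (male listed first, so a negative Z means males
#' discount delayed condom-protected sex more steeply). 4 rows.
#'
#' @inheritParams table1_analysis
#' @return A tibble like [table1_analysis()] with `group_a = "male"`,
#'   `group_b = "female"`.
#' @export
gender_contrast <- function(cohort, auc = NULL, ...) {
  if (is.null(auc)) auc <- cohort_auc(cohort, ...)
  dat <- dplyr::left_join(auc,
                          dplyr::select(cohort, "participant_id", "gender"),
                          by = "participant_id")
  rows <- lapply(sdt_conditions(), function(cond) {
    sub <- dplyr::filter(dat, .data$condition == cond, !is.na(.data$auc))
    a <- sub$auc[sub$gender == "male"]
    b <- sub$auc[sub$gender == "female"]
    if (length(a) < 2 || length(b) < 2) {
      return(tibble::tibble(condition = cond, group_a = "male",
                            group_b = "female", n_a = length(a),
                            n_b = length(b), mean_rank_diff = NA_real_,
                            z = NA_real_, p_two_sided = NA_real_,
                            note = "insufficient observations"))
    }
    wt <- suppressWarnings(wilcoxon_rank_sum(a, b))
    tibble::tibble(condition = cond, group_a = "male", group_b = "female",
                   n_a = wt$n_a, n_b = wt$n_b,
                   mean_rank_diff = wt$mean_rank_diff, z = wt$z,
                   p_two_sided = wt$p_two_sided, note = "")
  })
  out <- dplyr::bind_rows(rows)
  out$sig <- sig_marks(out$p_two_sided, 0.05, 0.001)
  out
}

#' Demographic summary of a cohort
#'
#' Medians and interquartile ranges (linear-interpolation quantiles) for
#' the numeric demographics, and proportions for the categorical ones.
#'
#' @param cohort A cohort tibble.
#' @return A list with tibbles `numeric` (`variable`, `median`, `q1`,
#'   `q3`, `n`) and `proportions` (`variable`, `level`, `proportion`).
#' @export
demographics_summary <- function(cohort) {
  num_vars <- intersect(c("age", "household_size", "income_usd",
                          "days_since_last_encounter", "image_count"),
                        names(cohort))
  numeric <- dplyr::bind_rows(lapply(num_vars, function(v) {
    m <- median_iqr(cohort[[v]])
    tibble::tibble(variable = v, median = m[["median"]], q1 = m[["q1"]],
                   q3 = m[["q3"]], n = sum(!is.na(cohort[[v]])))
  }))
  cat_vars <- intersect(c("gender", "scenario", "education",
                          "marital_status"), names(cohort))
  proportions <- dplyr::bind_rows(lapply(cat_vars, function(v) {
    tab <- table(cohort[[v]])
    tibble::tibble(variable = v, level = names(tab),
                   proportion = as.numeric(tab) / sum(tab))
  }))
  list(numeric = numeric, proportions = proportions)
}

#' Run the full analysis pipeline
#'
#' Loads or simulates a cohort, computes per-participant AUCs (or uses
#' precomputed ones), and produces the complete report bundle: the 15-row
#' pairwise scenario Wilcoxon table, the 12-row permutation table of
#' AUC-HRBS correlation differences, the 24-row Spearman correlation
#' panel, the 4-row gender contrast, the demographic summary, a median
#' indifference-point summary per delay x scenario x condition, and run
#' metadata (seeds, flags, input digest).
#'
#' @param config A list with either `simulate` (a [sim_config()]) or
#'   `input` (a file path) plus optional `mapping` (a
#'   [column_mapping()]); optional elements `n_resamples` (default
#'   100,000), `seed` (default 1), `auc_anchor` (default `"measured"`),
#'   `vas_mode` (default `"strict"`).
#' @param out_dir Optional directory; when given, each table is written
#'   as CSV plus a `metadata.json`.
#' @return An object of class `"sexdisc_report"`.
#' @export
run_all <- function(config, out_dir = NULL) {
  n_resamples <- config$n_resamples %||% 100000L
  seed <- config$seed %||% 1L
  auc_anchor <- config$auc_anchor %||% "measured"
  vas_mode <- config$vas_mode %||% "strict"

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(config$simulate)) {
    cohort <- stage("simulate", generate_cohort(config$simulate))
    vas_scale <- 100
    money_scale <- 1000
    input <- "simulated"
  } else if (!is.null(config$input)) {
    cohort <- stage("load", read_cohort_mapped(config$input, config$mapping))
    vas_scale <- attr(cohort, "vas_scale") %||% 100
    money_scale <- attr(cohort, "money_scale") %||% 1000
    input <- config$input
  } else {
    stop("config must name either a simulation config or an input file",
         call. = FALSE)
  }

  auc <- stage("auc", cohort_auc(cohort, auc_anchor = auc_anchor,
                                 vas_scale = vas_scale,
                                 money_scale = money_scale,
                                 vas_mode = vas_mode))
  table1 <- stage("table1", table1_analysis(cohort, auc = auc))
  table2 <- stage("table2", table2_analysis(cohort, auc = auc,
                                            n_resamples = n_resamples,
                                            seed = seed))
  table3 <- stage("table3", table3_analysis(cohort, auc = auc))
  gender <- stage("gender", gender_contrast(cohort, auc = auc))
  demographics <- stage("demographics", demographics_summary(cohort))
  medians <- stage("medians", median_indifference_points(
    cohort, vas_scale = vas_scale, money_scale = money_scale,
    vas_mode = vas_mode))

  metadata <- list(
    seed = as.integer(seed),
    n_resamples = as.integer(n_resamples),
    auc_anchor = auc_anchor,
    vas_mode = vas_mode,
    input = input,
    n_participants = nrow(cohort),
    n_curves_excluded = attr(auc, "n_excluded") %||% 0L,
    input_digest = rlang::hash(cohort),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  report <- structure(
    list(cohort = cohort, auc = auc, table1 = table1, table2 = table2,
         table3 = table3, gender_contrast = gender,
         demographics = demographics, median_curves = medians,
         metadata = metadata),
    class = "sexdisc_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Median indifference points per delay, scenario and condition
#'
#' The summary behind the median-curve panels: for each partner condition
#' (and the monetary task), the median indifference proportion at each
#' delay within each scenario group.
#'
#' @inheritParams cohort_curves
#' @return A tibble `condition`, `scenario`, `delay_hours`,
#'   `median_value`, `n`.
#' @export
median_indifference_points <- function(cohort, vas_scale = 100,
                                       money_scale = 1000,
                                       vas_mode = "strict") {
  cohort_curves(cohort, vas_scale = vas_scale, money_scale = money_scale,
                vas_mode = vas_mode) |>
    dplyr::left_join(dplyr::select(cohort, "participant_id", "scenario"),
                     by = "participant_id") |>
    dplyr::group_by(.data$condition, .data$scenario, .data$delay_hours) |>
    dplyr::summarise(median_value = stats::median(.data$value, na.rm = TRUE),
                     n = sum(!is.na(.data$value)), .groups = "drop")
}

#' Write a report bundle to disk
#'
#' One CSV per table plus `metadata.json`.
#'
#' @param report A `"sexdisc_report"` from [run_all()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$table1, file.path(out_dir, "table1_wilcoxon.csv"))
  readr::write_csv(report$table2, file.path(out_dir, "table2_perm_corr.csv"))
  readr::write_csv(report$table3, file.path(out_dir, "table3_spearman.csv"))
  readr::write_csv(report$gender_contrast,
                   file.path(out_dir, "gender_contrast.csv"))
  readr::write_csv(report$demographics$numeric,
                   file.path(out_dir, "demographics_numeric.csv"))
  readr::write_csv(report$demographics$proportions,
                   file.path(out_dir, "demographics_proportions.csv"))
  readr::write_csv(report$median_curves,
                   file.path(out_dir, "median_indifference_points.csv"))
  jsonlite::write_json(report$metadata, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.sexdisc_report <- function(x, ...) {
  cat("Sexual discounting analysis report\n")
  cat(sprintf("  %d participants (%s)\n", x$metadata$n_participants,
              x$metadata$input))
  cat(sprintf("  AUC anchor: %s; permutation resamples: %d; seed: %d\n",
              x$metadata$auc_anchor, x$metadata$n_resamples,
              x$metadata$seed))
  cat("  Tables: table1 (", nrow(x$table1), " rows), table2 (",
      nrow(x$table2), "), table3 (", nrow(x$table3),
      "), gender_contrast (", nrow(x$gender_contrast), ")\n", sep = "")
  sig1 <- sum(x$table1$p_two_sided < 0.05, na.rm = TRUE)
  cat(sprintf("  %d of %d scenario contrasts significant at 0.05\n",
              sig1, sum(!is.na(x$table1$p_two_sided))))
  invisible(x)
}
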