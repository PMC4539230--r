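#' Delay schedules for the discounting tasks
#'
#' The sexual discounting task (SDT) presents a zero-delay anchor trial
#' followed by seven delays to condom-protected sex; the monetary delay
#' discounting task (DDT) presents six delays to a $1000 reward. Durations
#' are expressed in hours using round calendar conversions (1 month = 30
#' days = 720 h, 1 year = 8760 h) so that normalized positions are
#' reproducible.
#'
#' @return A tibble with columns `label` and `delay_hours`, ordered by
#'   increasing delay.
#' @examples
#' sdt_schedule()
#' ddt_schedule()
#' @export
sdt_schedule <- function() {
  tibble::tibble(
    label = c("now", "1 hour", "3 hours", "6 hours", "1 day",
              "1 week", "1 month", "3 months"),
    delay_hours = c(0, 1, 3, 6, 24, 168, 720, 2160)
  )
}

#' @rdname sdt_schedule
#' @export
ddt_schedule <- function() {
  tibble::tibble(
    label = c("1 day", "1 week", "1 month", "3 months", "1 year", "5 years"),
    delay_hours = c(24, 168, 720, 2160, 8760, 43800)
  )
}

#' Partner conditions and scenario levels
#'
#' Canonical orderings used throughout the package: the four SDT partner
#' conditions (plus `"monetary"` where the DDT is analysed alongside them)
#' and the three scenario groups.
#'
#' @name levels
#' @export
sdt_conditions <- function() {
  c("least_attractive", "most_attractive", "least_sti", "most_sti")
}

#' @rdname levels
#' @export
all_conditions <- function() c(sdt_conditions(), "monetary")

#' @rdname levels
#' @export
scenario_levels <- function() c("positive", "negative", "negative_regret")

#' Normalize a delay schedule to unit positions
#'
#' Divides each duration by the maximum duration so the last position is 1.
#' These positions are the x-axis of the trapezoidal AUC.
#'
#' @param delay_hours Strictly increasing, non-negative delays in hours.
#' @return Numeric vector of positions in `[0, 1]`.
#' @examples
#' normalize_delays(c(0, 1080, 2160))  # 0, 0.5, 1
#' @export
normalize_delays <- function(delay_hours) {
  if (length(delay_hours) == 0) {
    stop("delay schedule is empty", call. = FALSE)
  }
  if (any(delay_hours < 0) || any(diff(delay_hours) <= 0)) {
    stop("delays must be non-negative and strictly increasing", call. = FALSE)
  }
  delay_hours / max(delay_hours)
}

#' Convert visual-analog-scale responses to proportions
#'
#' VAS responses are recorded 0-100 (0 = sex now without a condom,
#' 100 = delayed sex with a condom) and analysed as proportions.
#'
#' @param vas Numeric responses on the 0-100 scale.
#' @param mode `"strict"` errors on out-of-range values; `"lenient"` clips
#'   them into range and emits a warning with the number clipped.
#' @return Proportions in `[0, 1]`.
#' @export
vas_to_proportion <- function(vas, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  out_of_range <- !is.na(vas) & (vas < 0 | vas > 100)
  if (any(out_of_range)) {
    if (mode == "strict") {
      stop(sum(out_of_range), " VAS value(s) outside [0, 100]", call. = FALSE)
    }
    warning("clipped ", sum(out_of_range), " VAS value(s) into [0, 100]",
            call. = FALSE)
    vas <- pmin(pmax(vas, 0), 100)
  }
  vas / 100
}

#' Trapezoidal area under the discounting curve
#'
#' Computes the normalized area under each participant x condition
#' indifference curve: delays are scaled to `[0, 1]` by the maximum delay
#' and the curve is integrated by the trapezoid rule, giving an AUC in
#' `[0, 1]`. Lower AUC means steeper discounting (stronger preference for
#' the immediate option).
#'
#' Monetary curves receive a synthetic anchor point at position 0 with
#' value 1 before integration: the undelayed full amount is worth its face
#' value by definition. Sexual curves carry a measured zero-delay trial;
#' `auc_anchor = "exclude-zero"` drops that trial before integration for
#' sensitivity analyses.
#'
#' @param curves A tidy curve table with columns `participant_id`,
#'   `commodity` (`"sexual"` or `"monetary"`), `condition`, `delay_hours`,
#'   and `value` (proportion in `[0, 1]`).
#' @param auc_anchor `"measured"` (default) keeps the measured zero-delay
#'   SDT trial; `"exclude-zero"` drops it.
#' @param na_action `"exclude"` (default) drops a participant x condition
#'   curve containing any missing value and reports the count in the
#'   `n_excluded` attribute; `"error"` stops.
#' @return A tibble with columns `participant_id`, `condition`, `auc`,
#'   carrying attribute `n_excluded`.
#' @examples
#' curves <- tibble::tibble(
#'   participant_id = "p1", commodity = "sexual",
#'   condition = "most_attractive",
#'   delay_hours = sdt_schedule()$delay_hours,
#'   value = c(1, 1, 1, 1, 1, 1, 1, 0)
#' )
#' compute_auc(curves)$auc  # 0.666667
#' @export
compute_auc <- function(curves,
                        auc_anchor = c("measured", "exclude-zero"),
                        na_action = c("exclude", "error")) {
  auc_anchor <- match.arg(auc_anchor)
  na_action <- match.arg(na_action)
  required <- c("participant_id", "commodity", "condition",
                "delay_hours", "value")
  missing_cols <- setdiff(required, names(curves))
  if (length(missing_cols) > 0) {
    stop("curve table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ok <- !is.na(curves$value)
  if (any(curves$value[ok] < 0 | curves$value[ok] > 1)) {
    stop("curve values must be proportions in [0, 1]", call. = FALSE)
  }

  grouped <- dplyr::group_by(curves, .data$participant_id, .data$condition)
  incomplete <- dplyr::summarise(grouped,
                                 any_na = anyNA(.data$value),
                                 .groups = "drop")
  n_excluded <- sum(incomplete$any_na)
  if (n_excluded > 0 && na_action == "error") {
    stop(n_excluded, " curve(s) contain missing responses", call. = FALSE)
  }

  out <- grouped |>
    dplyr::filter(!anyNA(.data$value)) |>
    dplyr::arrange(.data$delay_hours, .by_group = TRUE) |>
    dplyr::summarise(
      auc = auc_trapezoid(.data$delay_hours, .data$value,
                          commodity = .data$commodity[1],
                          auc_anchor = auc_anchor),
      .groups = "drop"
    )
  attr(out, "n_excluded") <- n_excluded
  out
}

# Trapezoid AUC for one sorted curve. Monetary curves get the (0, 1)
# anchor; sexual curves optionally drop the measured zero-delay trial.
auc_trapezoid <- function(delay_hours, value, commodity, auc_anchor) {
  if (commodity == "monetary") {
    if (delay_hours[1] != 0) {
      delay_hours <- c(0, delay_hours)
      value <- c(1, value)
    }
  } else if (auc_anchor == "exclude-zero" && delay_hours[1] == 0) {
    keep <- -1L
    delay_hours <- delay_hours[keep]
    value <- value[keep]
    # re-origin: remaining delays keep their absolute scale
  }
  if (length(delay_hours) < 2) {
    stop("need at least 2 points to integrate a curve", call. = FALSE)
  }
  x <- normalize_delays(delay_hours)
  sum(diff(x) * (utils::head(value, -1) + utils::tail(value, -1)) / 2) /
    (max(x) - min(x))
}

#' Consistency check for monetary discounting curves
#'
#' Flags monetary indifference-point sets that fail either of two
#' conventional criteria for orderly discounting data: (a) any
#' indifference point rising more than 0.20 of the delayed amount above
#' its predecessor, or (b) the last point failing to fall at least 0.10
#' below the first.
#'
#' @param values Six indifference proportions (indifference point / 1000),
#'   ordered by increasing delay.
#' @return A list with `pass` (logical) and `reasons` (character vector of
#'   violated criteria, empty when passing).
#' @export
check_ddt_consistency <- function(values) {
  if (length(values) != 6) {
    stop("monetary curve must have 6 indifference points", call. = FALSE)
  }
  reasons <- character()
  if (any(diff(values) > 0.20)) {
    reasons <- c(reasons,
                 "an indifference point exceeds its predecessor by more than 0.20")
  }
  if (values[length(values)] > values[1] - 0.10) {
    reasons <- c(reasons,
                 "last indifference point is not at least 0.10 below the first")
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Read and write tidy curve tables
#'
#' Curves serialize to a tidy comma-separated layout with columns
#' `participant_id`, `commodity`, `condition`, `delay_hours`, `value`
#' (proportion in `[0, 1]`), UTF-8 with a header row.
#'
#' @param curves A tidy curve table (see [compute_auc()]).
#' @param path File path.
#' @return `read_curves()` returns the curve tibble; `write_curves()`
#'   returns `path` invisibly.
#' @export
write_curves <- function(curves, path) {
  readr::write_csv(curves, path)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    commodity = readr::col_character(),
    condition = readr::col_character(),
    delay_hours = readr::col_double(),
    value = readr::col_double()
  ))
}
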