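#' Questionnaire scoring configuration
#'
#' The four self-report instruments are scored from item-level responses:
#'
#' * HRBS — HIV Risk Taking Behavior Scale, 11 items scored 0-5, total is
#'   the sum (range 0-55); higher = more HIV risk behavior.
#' * ZTPI future subscale — 12 retained items (one item of the 13-item
#'   future-orientation subscale was not recorded) scored 1-5, total is
#'   the mean after reverse-scoring (range 1-5); higher = more future
#'   oriented.
#' * SSS — Short Suggestibility Scale, 21 items scored 1-5, total is the
#'   sum (range 21-105).
#' * CFC — Consideration of Future Consequences, 12 items scored 1-5,
#'   mean (default) or sum after reverse-scoring; higher = more
#'   consideration of future consequences.
#'
#' Reverse-scored item positions are configuration, not hard-coded: the
#' published keys are supplied as defaults and the active key should be
#' logged with every run. Reversal maps a response `r` on a 1-5 item to
#' `6 - r`.
#'
#' @param ztpi_reversals Integer positions (within the 12 retained items)
#'   reverse-scored for the ZTPI future subscale.
#' @param cfc_reversals Integer positions reverse-scored for the CFC.
#' @param cfc_aggregate `"mean"` (default) or `"sum"` for the CFC total.
#' @return A list of class `"questionnaire_key"`.
#' @export
questionnaire_key <- function(ztpi_reversals = c(3, 6, 7, 12),
                              cfc_reversals = c(3, 4, 5, 9, 10, 11, 12),
                              cfc_aggregate = c("mean", "sum")) {
  cfc_aggregate <- match.arg(cfc_aggregate)
  structure(list(ztpi_reversals = as.integer(ztpi_reversals),
                 cfc_reversals = as.integer(cfc_reversals),
                 cfc_aggregate = cfc_aggregate),
            class = "questionnaire_key")
}

check_items <- function(items, n, lo, hi, instrument) {
  if (length(items) != n) {
    stop(instrument, " requires ", n, " items, got ", length(items),
         call. = FALSE)
  }
  if (anyNA(items) || any(items < lo | items > hi)) {
    stop(instrument, " items must lie in ", lo, "-", hi, call. = FALSE)
  }
  invisible(items)
}

reverse_items <- function(items, positions) {
  items[positions] <- 6 - items[positions]
  items
}

#' Score the HRBS (sum of 11 items, range 0-55)
#'
#' @param items Integer responses; see [questionnaire_key()] for the
#'   instrument layouts.
#' @return Numeric total score.
#' @export
score_hrbs <- function(items) {
  check_items(items, 11, 0, 5, "HRBS")
  sum(items)
}

#' Score the ZTPI future subscale (mean of 12 retained items, range 1-5)
#'
#' @inheritParams score_hrbs
#' @param key A [questionnaire_key()]; its `ztpi_reversals` are applied
#'   before averaging.
#' @export
score_ztpi_future <- function(items, key = questionnaire_key()) {
  check_items(items, 12, 1, 5, "ZTPI future subscale")
  mean(reverse_items(items, key$ztpi_reversals))
}

#' Score the SSS (sum of 21 items, range 21-105)
#'
#' @inheritParams score_hrbs
#' @export
score_sss <- function(items) {
  check_items(items, 21, 1, 5, "SSS")
  sum(items)
}

#' Score the CFC (mean or sum of 12 items after reversals)
#'
#' @inheritParams score_ztpi_future
#' @export
score_cfc <- function(items, key = questionnaire_key()) {
  check_items(items, 12, 1, 5, "CFC")
  items <- reverse_items(items, key$cfc_reversals)
  if (key$cfc_aggregate == "sum") sum(items) else mean(items)
}

#' Score all instruments present in a cohort table
#'
#' Looks for item-level columns named `<instrument>_item_<k>` (lower-case
#' instrument: `hrbs`, `ztpi`, `sss`, `cfc`) and appends one
#' `<instrument>_score` column per instrument found. Instruments whose
#' item columns are absent are left untouched (their scores may already
#' be present).
#'
#' @param data A data frame of participant records.
#' @param key A [questionnaire_key()].
#' @return `data` with score columns appended, as a tibble.
#' @export
score_questionnaires <- function(data, key = questionnaire_key()) {
  data <- tibble::as_tibble(data)
  specs <- list(
    hrbs = list(n = 11, fn = function(it) score_hrbs(it)),
    ztpi = list(n = 12, fn = function(it) score_ztpi_future(it, key)),
    sss  = list(n = 21, fn = function(it) score_sss(it)),
    cfc  = list(n = 12, fn = function(it) score_cfc(it, key))
  )
  for (ins in names(specs)) {
    cols <- paste0(ins, "_item_", seq_len(specs[[ins]]$n))
    if (all(cols %in% names(data))) {
      mat <- as.matrix(data[cols])
      data[[paste0(ins, "_score")]] <-
        apply(mat, 1, specs[[ins]]$fn)
    }
  }
  data
}
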