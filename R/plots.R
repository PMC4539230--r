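#' Plot median indifference-point curves
#'
#' One panel per partner condition: median indifference proportion at
#' each delay, one line per scenario group. Delays are shown on the
#' normalized position axis used by the AUC.
#'
#' @param cohort A cohort tibble, or a precomputed
#'   [median_indifference_points()] table.
#' @param conditions Conditions to show (default the four sexual ones).
#' @param ... Passed to [median_indifference_points()] when `cohort` is a
#'   raw cohort.
#' @return A ggplot object.
#' @export
plot_median_curves <- function(cohort, conditions = sdt_conditions(), ...) {
  med <- if (all(c("median_value", "delay_hours") %in% names(cohort))) {
    cohort
  } else {
    median_indifference_points(cohort, ...)
  }
  med <- dplyr::filter(med, .data$condition %in% conditions)
  med <- med |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(position = .data$delay_hours / max(.data$delay_hours)) |>
    dplyr::ungroup()
  ggplot2::ggplot(med, ggplot2::aes(x = .data$position,
                                    y = .data$median_value,
                                    colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "normalized delay", y = "median indifference point",
                  colour = "scenario") +
    ggplot2::theme_minimal()
}

#' Plot AUC distributions by scenario
#'
#' Boxplots of per-participant AUC for each condition, split by scenario,
#' with the individual values overplotted (jittered).
#'
#' @param cohort A cohort tibble.
#' @param conditions Conditions to show.
#' @param ... Passed to [cohort_auc()].
#' @return A ggplot object.
#' @export
plot_auc_distributions <- function(cohort, conditions = sdt_conditions(),
                                   ...) {
  auc <- cohort_auc(cohort, ...) |>
    dplyr::left_join(dplyr::select(cohort, "participant_id", "scenario"),
                     by = "participant_id") |>
    dplyr::filter(.data$condition %in% conditions)
  ggplot2::ggplot(auc, ggplot2::aes(x = .data$scenario, y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.25, size = 0.6) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = NULL, y = "AUC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.sexdisc_report <- function(object, type = c("medians", "auc"),
                                    ...) {
  type <- match.arg(type)
  if (type == "medians") plot_median_curves(object$median_curves, ...)
  else plot_auc_distributions(object$cohort, ...)
}
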