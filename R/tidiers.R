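#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Wilcoxon rank-sum result
#'
#' @param x A `"wilcoxon_rs"` object.
#' @param ... Unused.
#' @return A one-row tibble with `z`, `p_two_sided`, `n_a`, `n_b`, `w`,
#'   `mean_rank_diff`.
#' @export
tidy.wilcoxon_rs <- function(x, ...) {
  tibble::tibble(z = x$z, p_two_sided = x$p_two_sided, n_a = x$n_a,
                 n_b = x$n_b, w = x$w, mean_rank_diff = x$mean_rank_diff)
}

#' Tidy a Spearman correlation result
#'
#' @param x A `"spearman_cor"` object.
#' @param ... Unused.
#' @export
tidy.spearman_cor <- function(x, ...) {
  tibble::tibble(rho = x$rho, p_two_sided = x$p_two_sided, n = x$n,
                 degenerate = x$degenerate)
}

#' Tidy a permutation correlation-difference result
#'
#' @param x A `"perm_corr_diff"` object.
#' @param ... Unused.
#' @export
tidy.perm_corr_diff <- function(x, ...) {
  tibble::tibble(rho_a = x$rho_a, rho_b = x$rho_b,
                 observed_diff = x$observed_diff,
                 p_two_sided = x$p_two_sided, n_resamples = x$n_resamples,
                 n_degenerate = x$n_degenerate, seed = x$seed,
                 exhaustive = x$exhaustive)
}

#' One-row summary of a report bundle
#'
#' @param x A `"sexdisc_report"`.
#' @param ... Unused.
#' @return A one-row tibble: participant count, excluded-curve count,
#'   counts of significant rows per table, and the run seed.
#' @export
glance.sexdisc_report <- function(x, ...) {
  tibble::tibble(
    n_participants = x$metadata$n_participants,
    n_curves_excluded = x$metadata$n_curves_excluded,
    table1_sig_05 = sum(x$table1$p_two_sided < 0.05, na.rm = TRUE),
    table2_sig_05 = sum(x$table2$p_two_sided < 0.05, na.rm = TRUE),
    table3_sig_05 = sum(x$table3$p_two_sided < 0.05, na.rm = TRUE),
    seed = x$metadata$seed,
    n_resamples = x$metadata$n_resamples
  )
}
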