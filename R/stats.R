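#' Average ranks with ties
#'
#' Midranks: tied values receive the mean of the integer ranks they span,
#' so ranks always sum to `n(n+1)/2`.
#'
#' @param values Numeric vector, non-empty.
#' @return Numeric vector of midranks.
#' @export
rank_with_ties <- function(values) {
  if (length(values) == 0) stop("cannot rank an empty vector", call. = FALSE)
  rank(values, ties.method = "average")
}

#' Tie-corrected Wilcoxon rank-sum Z test
#'
#' Large-sample Wilcoxon rank-sum test with the tie-corrected variance and
#' no continuity correction. With `W` the rank sum of the first group in
#' the joint midranking of both samples,
#' \deqn{Z = \frac{W - n_a(n+1)/2}{\sqrt{\frac{n_a n_b}{12}\left[(n+1) -
#'   \frac{\sum(t^3 - t)}{n(n-1)}\right]}}}
#' where the sum runs over tie groups of size `t`. The sign follows the
#' first-listed group: negative Z means the first group ranks lower. The
#' two-sided p comes from the standard normal.
#'
#' When every pooled value is identical the statistic is defined as
#' `z = 0`, `p = 1`, with a warning.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param continuity Apply the 0.5 continuity correction (default off,
#'   matching the uncorrected tie-adjusted Z convention used throughout).
#' @return An object of class `"wilcoxon_rs"`: a list with `z`,
#'   `p_two_sided`, `n_a`, `n_b`, `w` (rank sum of the first group), and
#'   `mean_rank_diff` (mean joint rank of the first group minus the
#'   second, a descriptive analogue of a score mean difference).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$z  # about -1.964
#' @export
wilcoxon_rank_sum <- function(group_a, group_b, continuity = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  n <- n_a + n_b
  pooled <- c(group_a, group_b)
  r <- rank_with_ties(pooled)
  w <- sum(r[seq_len(n_a)])
  expected <- n_a * (n + 1) / 2
  tie_sizes <- tabulate(match(pooled, unique(pooled)))
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (n * (n - 1))
  variance <- n_a * n_b / 12 * ((n + 1) - tie_term)
  mean_rank_diff <- w / n_a - sum(r[n_a + seq_len(n_b)]) / n_b
  if (variance <= 0) {
    warning("all pooled values identical; returning z = 0, p = 1",
            call. = FALSE)
    z <- 0
    p <- 1
  } else {
    num <- w - expected
    if (continuity) num <- num - sign(num) * 0.5
    z <- num / sqrt(variance)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(z = z, p_two_sided = p, n_a = n_a, n_b = n_b, w = w,
         mean_rank_diff = mean_rank_diff),
    class = "wilcoxon_rs"
  )
}

#' Spearman rank correlation with t-approximation p-value
#'
#' The rank correlation is the product-moment correlation of midranks;
#' the two-sided p-value uses the t approximation with `n - 2` degrees of
#' freedom. When either vector has zero rank variance the correlation is
#' undefined and the result is flagged degenerate (`rho = NA`).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return An object of class `"spearman_cor"`: a list with `rho`,
#'   `p_two_sided`, `n`, and `degenerate`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  rx <- rank_with_ties(x)
  ry <- rank_with_ties(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(structure(list(rho = NA_real_, p_two_sided = NA_real_, n = n,
                          degenerate = TRUE),
                     class = "spearman_cor"))
  }
  rho <- stats::cor(rx, ry)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (is.nan(tstat)) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(rho = rho, p_two_sided = p, n = n, degenerate = FALSE),
            class = "spearman_cor")
}

#' Observed difference in Spearman correlation between two groups
#'
#' @param x_a,y_a Paired observations for the first group.
#' @param x_b,y_b Paired observations for the second group.
#' @return `spearman_corr(x_a, y_a)$rho - spearman_corr(x_b, y_b)$rho`.
#' @export
corr_diff_statistic <- function(x_a, y_a, x_b, y_b) {
  spearman_corr(x_a, y_a)$rho - spearman_corr(x_b, y_b)$rho
}

#' Permutation test for a difference in correlation strength
#'
#' Tests whether the Spearman correlation between two variables differs
#' between two independent groups. Pairs `(x, y)` stay intact; only the
#' group labels are randomly reassigned (preserving group sizes) a large
#' number of times, the correlation difference is recomputed for each
#' relabeling, and the two-sided p-value is the proportion of resampled
#' absolute differences at least as large as the observed absolute
#' difference.
#'
#' A resample in which either relabeled group has zero rank variance
#' contributes a null difference of 0 and is tallied in `n_degenerate`.
#'
#' @param x_a,y_a,x_b,y_b Paired observations per group (>= 3 pairs each).
#' @param n_resamples Number of random relabelings (default 100,000).
#' @param seed Integer seed; recorded in the result. `NULL` leaves the RNG
#'   state untouched (the result then records `NA`).
#' @param plus_one Use the `(count + 1) / (B + 1)` estimator instead of
#'   the plain proportion (default off).
#' @param engine `"cpp"` (default) uses the compiled resampling engine;
#'   `"r"` is a plain-R reference loop.
#' @return An object of class `"perm_corr_diff"`: a list with `rho_a`,
#'   `rho_b`, `observed_diff`, `p_two_sided`, `n_resamples`,
#'   `n_degenerate`, `seed`, and `exhaustive = FALSE`.
#' @seealso [exhaustive_corr_diff_null()] for the exact small-sample
#'   enumeration.
#' @export
permutation_corr_diff <- function(x_a, y_a, x_b, y_b,
                                  n_resamples = 100000L, seed = NULL,
                                  plus_one = FALSE,
                                  engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (n_resamples < 1) stop("n_resamples must be >= 1", call. = FALSE)
  rho_a <- spearman_corr(x_a, y_a)$rho
  rho_b <- spearman_corr(x_b, y_b)$rho
  if (is.na(rho_a) || is.na(rho_b)) {
    stop("observed correlation undefined (zero rank variance)",
         call. = FALSE)
  }
  observed <- rho_a - rho_b
  n_a <- length(x_a)
  x <- c(x_a, x_b)
  y <- c(y_a, y_b)
  if (!is.null(seed)) set.seed(seed)
  if (engine == "cpp") {
    res <- perm_corr_diff_engine(x, y, n_a, as.integer(n_resamples))
    null_diffs <- res$null_diffs
    n_degenerate <- res$n_degenerate
  } else {
    n <- length(x)
    null_diffs <- numeric(n_resamples)
    n_degenerate <- 0L
    for (b in seq_len(n_resamples)) {
      idx <- sample.int(n)
      ia <- idx[seq_len(n_a)]
      ib <- idx[-seq_len(n_a)]
      ra <- suppressWarnings(spearman_rho_cpp(x[ia], y[ia]))
      rb <- suppressWarnings(spearman_rho_cpp(x[ib], y[ib]))
      if (is.na(ra) || is.na(rb)) {
        null_diffs[b] <- 0
        n_degenerate <- n_degenerate + 1L
      } else {
        null_diffs[b] <- ra - rb
      }
    }
  }
  count <- sum(abs(null_diffs) >= abs(observed) - 1e-12)
  p <- if (plus_one) (count + 1) / (n_resamples + 1) else count / n_resamples
  structure(
    list(rho_a = rho_a, rho_b = rho_b, observed_diff = observed,
         p_two_sided = p, n_resamples = as.integer(n_resamples),
         n_degenerate = as.integer(n_degenerate),
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         exhaustive = FALSE),
    class = "perm_corr_diff"
  )
}

#' Exact permutation null by exhaustive relabeling
#'
#' Enumerates every assignment of the pooled pairs into groups of sizes
#' `n_a` and `n_b` exactly once and returns the exact two-sided p-value:
#' the proportion of relabelings whose absolute correlation difference is
#' at least the observed absolute difference. Usable when
#' `choose(n_a + n_b, n_a) <= 1e6`; larger problems are directed to the
#' Monte-Carlo path.
#'
#' @inheritParams permutation_corr_diff
#' @return An object of class `"perm_corr_diff"` with
#'   `exhaustive = TRUE`, `n_resamples` the number of relabelings, and
#'   `seed = NA` (no randomness).
#' @export
exhaustive_corr_diff_null <- function(x_a, y_a, x_b, y_b) {
  n_a <- length(x_a)
  n_b <- length(x_b)
  n <- n_a + n_b
  n_comb <- choose(n, n_a)
  if (n_comb > 1e6) {
    stop("choose(n, n_a) = ", n_comb,
         " exceeds 1e6; use permutation_corr_diff()", call. = FALSE)
  }
  rho_a <- spearman_corr(x_a, y_a)$rho
  rho_b <- spearman_corr(x_b, y_b)$rho
  observed <- rho_a - rho_b
  x <- c(x_a, x_b)
  y <- c(y_a, y_b)
  combs <- utils::combn(n, n_a)
  n_degenerate <- 0L
  null_diffs <- apply(combs, 2, function(ia) {
    ib <- setdiff(seq_len(n), ia)
    ra <- spearman_rho_cpp(x[ia], y[ia])
    rb <- spearman_rho_cpp(x[ib], y[ib])
    if (is.na(ra) || is.na(rb)) NA_real_ else ra - rb
  })
  n_degenerate <- sum(is.na(null_diffs))
  null_diffs[is.na(null_diffs)] <- 0
  p <- mean(abs(null_diffs) >= abs(observed) - 1e-12)
  structure(
    list(rho_a = rho_a, rho_b = rho_b, observed_diff = observed,
         p_two_sided = p, n_resamples = as.integer(n_comb),
         n_degenerate = as.integer(n_degenerate), seed = NA_integer_,
         exhaustive = TRUE),
    class = "perm_corr_diff"
  )
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7), a single stated convention so that
#' demographic summaries are reproducible.
#'
#' @param values Non-empty numeric vector (missing values dropped).
#' @return Named numeric vector `c(median, q1, q3)`.
#' @examples
#' median_iqr(1:4)  # 2.5, 1.75, 3.25
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no non-missing values", call. = FALSE)
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' @export
print.wilcoxon_rs <- function(x, ...) {
  cat("Wilcoxon rank-sum (tie-corrected normal approximation)\n")
  cat(sprintf("  n = %d vs %d, W = %.1f\n", x$n_a, x$n_b, x$w))
  cat(sprintf("  Z = %.3f, two-sided p = %.4g\n", x$z, x$p_two_sided))
  invisible(x)
}

#' @export
print.spearman_cor <- function(x, ...) {
  if (x$degenerate) {
    cat("Spearman correlation: undefined (zero rank variance), n =",
        x$n, "\n")
  } else {
    cat(sprintf("Spearman rho = %.4f, n = %d, two-sided p = %.4g\n",
                x$rho, x$n, x$p_two_sided))
  }
  invisible(x)
}

#' @export
print.perm_corr_diff <- function(x, ...) {
  kind <- if (x$exhaustive) "exhaustive" else "Monte-Carlo"
  cat(sprintf("Permutation test for correlation difference (%s)\n", kind))
  cat(sprintf("  rho_a = %.4f, rho_b = %.4f, diff = %.4f\n",
              x$rho_a, x$rho_b, x$observed_diff))
  cat(sprintf("  p (two-sided) = %.4g over %d relabelings\n",
              x$p_two_sided, x$n_resamples))
  if (x$n_degenerate > 0) {
    cat("  degenerate resamples counted as 0:", x$n_degenerate, "\n")
  }
  invisible(x)
}
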