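pb_slope <- function(x, y) {
  n <- length(x)
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  keep <- upper.tri(dx)
  dx <- dx[keep]
  dy <- dy[keep]
  s <- dy / dx
  # exclusion rule of the original procedure: drop slopes exactly -1 and
  # undefined slopes (dx == 0 with dy != 0); dx == dy == 0 contributes
  # nothing and is not counted as excluded
  undefined <- dx == 0 & dy != 0
  degenerate <- dx == 0 & dy == 0
  minus_one <- !is.na(s) & !degenerate & s == -1
  excluded <- sum(undefined) + sum(minus_one)
  s <- s[!(undefined | degenerate | minus_one)]
  if (length(s) == 0) {
    return(list(slope = NA_real_, excluded = excluded, n_kept = 0L))
  }
  s <- sort(s)
  N <- length(s)
  K <- sum(s < -1)
  slope <- if (N %% 2 == 1) {
    s[(N + 1) %/% 2 + K]
  } else {
    mean(s[c(N %/% 2 + K, N %/% 2 + 1 + K)])
  }
  list(slope = slope, excluded = excluded, n_kept = N)
}

#' Passing-Bablok method-comparison regression
#'
#' Nonparametric regression for comparing two measurement methods on the
#' same samples (robust to measurement error in both axes and to outliers).
#' The slope is the shifted median of all pairwise slopes
#' `S_ij = (y_j - y_i)/(x_j - x_i)`, i < j, after excluding slopes equal to
#' -1 and undefined slopes; the median rank is offset by K, the number of
#' kept slopes below -1, which makes the estimate invariant under exchange
#' of the two methods. The intercept is `median(y - slope * x)`.
#' 95% confidence intervals for slope and intercept are obtained by
#' percentile bootstrap over paired resamples.
#'
#' @param x,y Paired measurements from the two centers/methods (at least
#'   3 pairs; `x` not all identical).
#' @param n_boot Bootstrap replicates for the CIs (default 2000); 0 skips
#'   the bootstrap.
#' @param seed Integer seed for the bootstrap.
#' @param conf_level Confidence level (default 0.95).
#' @return A `pb_fit` object: list with `slope`, `intercept`, `slope_ci`,
#'   `intercept_ci`, `pearson_r`, `n_pairs`, `excluded_slopes`, `n_boot`.
#' @examples
#' fit <- passing_bablok_fit(1:5, 2 * (1:5), n_boot = 200, seed = 1)
#' fit$slope
#' @export
passing_bablok_fit <- function(x, y, n_boot = 2000, seed = 1,
                               conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (all(x == x[1])) stop("x values are all identical", call. = FALSE)

  est <- pb_slope(x, y)
  if (est$n_kept == 0) {
    stop("degenerate data: all pairwise slopes excluded", call. = FALSE)
  }
  slope <- est$slope
  intercept <- median(y - slope * x)
  r <- suppressWarnings(cor(x, y))

  slope_ci <- c(NA_real_, NA_real_)
  intercept_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    bs <- matrix(NA_real_, n_boot, 2)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx]; yb <- y[idx]
      if (all(xb == xb[1])) next
      eb <- pb_slope(xb, yb)
      if (eb$n_kept == 0 || !is.finite(eb$slope)) next
      bs[b, 1] <- eb$slope
      bs[b, 2] <- median(yb - eb$slope * xb)
    }
    alpha <- (1 - conf_level) / 2
    slope_ci <- unname(quantile(bs[, 1], c(alpha, 1 - alpha), na.rm = TRUE))
    intercept_ci <- unname(quantile(bs[, 2], c(alpha, 1 - alpha),
                                    na.rm = TRUE))
  }

  structure(list(
    slope = slope, intercept = intercept,
    slope_ci = slope_ci, intercept_ci = intercept_ci,
    pearson_r = r, n_pairs = n,
    excluded_slopes = est$excluded, n_boot = n_boot
  ), class = "pb_fit")
}

#' @export
print.pb_fit <- function(x, ...) {
  cat(sprintf(
    "Passing-Bablok fit (n = %d pairs)\n  slope     %.4f  [%.4f, %.4f]\n  intercept %.4f  [%.4f, %.4f]\n  Pearson r %.4f\n",
    x$n_pairs, x$slope, x$slope_ci[1], x$slope_ci[2],
    x$intercept, x$intercept_ci[1], x$intercept_ci[2], x$pearson_r))
  invisible(x)
}

#' Declare whether two centers' measurements are mergeable
#'
#' Applies the package's mergeability rule to a Passing-Bablok fit: an
#' analyte is mergeable when the slope CI contains 1 and either the
#' intercept CI contains 0 or the absolute intercept is small relative to
#' the measured values (below `intercept_frac` of the median measurement,
#' 5% by default) - a small systematic offset need not preclude pooling.
#'
#' @param fit A `pb_fit`.
#' @param values The measured values (used for the relative-intercept
#'   escape hatch); e.g. `c(x, y)`.
#' @param intercept_frac Relative-intercept threshold (default 0.05).
#' @return Logical scalar with attribute `reasons`.
#' @export
pb_mergeable <- function(fit, values, intercept_frac = 0.05) {
  slope_ok <- fit$slope_ci[1] <= 1 && 1 <= fit$slope_ci[2]
  int_null <- fit$intercept_ci[1] <= 0 && 0 <= fit$intercept_ci[2]
  int_small <- abs(fit$intercept) < intercept_frac * median(abs(values))
  structure(slope_ok && (int_null || int_small),
            reasons = c(slope_ci_contains_1 = slope_ok,
                        intercept_ci_contains_0 = int_null,
                        intercept_relatively_small = int_small))
}
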