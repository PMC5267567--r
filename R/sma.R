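#' Standardized major-axis (SMA) regression with slope-equals-one test
#'
#' Fits the standardized major axis (also called reduced major axis) of `y`
#' on `x`: the line whose slope is `sign(r) * s_y / s_x`, appropriate when
#' both variables carry error, as with male and female body sizes. In
#' Rensch's-rule analyses `x` is log female size and `y` is log male size,
#' so a slope above 1 means dimorphism grows with size in male-larger
#' lineages.
#'
#' The 1-alpha confidence interval for the slope is
#' `b * (sqrt(B + 1) +/- sqrt(B))` with
#' `B = F(1 - alpha; 1, n - 2) * (1 - r^2) / (n - 2)`. The test of slope = 1
#' uses the correlation `r_rf` between the residual axis `y - x` and the
#' fitted axis `y + x`; `F = r_rf^2 (n - 2) / (1 - r_rf^2)` is referred to
#' `F(1, n - 2)`. This test inverts exactly to the confidence interval, so
#' `p < alpha` if and only if 1 lies outside the interval — for positive
#' fitted slopes. The statistic depends on the data only through the ratio
#' of the axis standard deviations, so it addresses the slope's magnitude:
#' with a negative fitted slope (never the case for male-female size
#' allometry) a test against +1 is not meaningful and the CI alone should
#' be read.
#'
#' @param x,y Finite numeric vectors of equal length, `n >= 3`, each with
#'   nonzero variance.
#' @param alpha Test level for the CI and the slope-equals-one test;
#'   default 0.05.
#' @return An object of class `sma_fit`: list with `n`, `slope`,
#'   `intercept`, `r_squared`, `ci_low`, `ci_high`, `p_slope_eq_1`, `alpha`,
#'   `through_origin = FALSE`.
#' @seealso [sma_fit_through_origin()] for contrasts, [classify_allometry()]
#'   for the Rensch verdict.
#' @examples
#' set.seed(1)
#' f <- rnorm(50, 3, 0.5)
#' m <- 0.1 + 1.1 * f + rnorm(50, 0, 0.1)
#' sma_fit(f, m)
#' @export
sma_fit <- function(x, y, alpha = 0.05) {
  check_xy(x, y, min_n = 3)
  n <- length(x)
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    stop("degenerate input: zero variance on an axis", call. = FALSE)
  r <- stats::cor(x, y)
  slope <- (if (r < 0) -1 else 1) * sy / sx
  intercept <- mean(y) - slope * mean(x)
  r2 <- min(r^2, 1)  # guard floating overshoot on exact lines

  B <- stats::qf(1 - alpha, 1, n - 2) * (1 - r2) / (n - 2)
  bounds <- slope * c(sqrt(B + 1) - sqrt(B), sqrt(B + 1) + sqrt(B))

  p <- sma_slope_test_p(y - x, y + x, df = n - 2, centered = TRUE)

  structure(list(
    n = n, slope = slope, intercept = intercept, r_squared = r2,
    ci_low = min(bounds), ci_high = max(bounds),
    p_slope_eq_1 = p, alpha = alpha, through_origin = FALSE
  ), class = "sma_fit")
}

#' Through-origin SMA regression for independent contrasts
#'
#' Phylogenetic independent contrasts have arbitrary sign and no meaningful
#' mean, so their allometric line is constrained through the origin. The
#' slope is `sign(sum(x*y)) * sqrt(sum(y^2) / sum(x^2))`; `n - 1` degrees of
#' freedom replace `n - 2` in the CI and the slope-equals-one test, and
#' r-squared is the squared uncentered correlation
#' `(sum(x*y))^2 / (sum(x^2) * sum(y^2))` (not comparable to a centered
#' r-squared).
#'
#' @param x,y Contrast vectors of equal length, `n >= 2`; `x` not all zero.
#' @inheritParams sma_fit
#' @return An `sma_fit` object with `intercept = NA` and
#'   `through_origin = TRUE`.
#' @export
sma_fit_through_origin <- function(x, y, alpha = 0.05) {
  check_xy(x, y, min_n = 2)
  n <- length(x)
  sxx <- sum(x^2)
  syy <- sum(y^2)
  sxy <- sum(x * y)
  if (sxx == 0)
    stop("degenerate input: all x contrasts are zero", call. = FALSE)
  if (syy == 0)
    stop("degenerate input: all y contrasts are zero", call. = FALSE)
  slope <- (if (sxy < 0) -1 else 1) * sqrt(syy / sxx)
  r2 <- min(sxy^2 / (sxx * syy), 1)

  df <- n - 1
  B <- stats::qf(1 - alpha, 1, df) * (1 - r2) / df
  bounds <- slope * c(sqrt(B + 1) - sqrt(B), sqrt(B + 1) + sqrt(B))

  p <- sma_slope_test_p(y - x, y + x, df = df, centered = FALSE)

  structure(list(
    n = n, slope = slope, intercept = NA_real_, r_squared = r2,
    ci_low = min(bounds), ci_high = max(bounds),
    p_slope_eq_1 = p, alpha = alpha, through_origin = TRUE
  ), class = "sma_fit")
}

# One-sample SMA slope test against slope = 1, via the residual-vs-fitted
# axes correlation; uncentered cross-products for the through-origin case.
sma_slope_test_p <- function(resid_axis, fitted_axis, df, centered) {
  if (centered) {
    sr <- stats::sd(resid_axis)
    sf <- stats::sd(fitted_axis)
    if (sr == 0 || sf == 0) return(if (sr == 0) 1 else 0)
    r <- stats::cor(resid_axis, fitted_axis)
  } else {
    srr <- sum(resid_axis^2)
    sff <- sum(fitted_axis^2)
    if (srr == 0) return(1)       # y identical to x: slope is exactly 1
    if (sff == 0) return(0)       # y = -x: slope -1, maximally far from 1
    r <- sum(resid_axis * fitted_axis) / sqrt(srr * sff)
  }
  r2 <- min(r^2, 1)
  if (r2 >= 1) return(0)
  Fstat <- r2 * df / (1 - r2)
  stats::pf(Fstat, 1, df, lower.tail = FALSE)
}

#' @export
print.sma_fit <- function(x, ...) {
  kind <- if (x$through_origin) "SMA (through origin)" else "SMA"
  cat(kind, " fit, n = ", x$n, "\n", sep = "")
  cat(sprintf("  slope = %.4g  %g%% CI [%.4g, %.4g]\n",
              x$slope, 100 * (1 - x$alpha), x$ci_low, x$ci_high))
  if (!x$through_origin)
    cat(sprintf("  intercept = %.4g\n", x$intercept))
  cat(sprintf("  r^2 = %.4g,  P(slope = 1) = %.3g\n",
              x$r_squared, x$p_slope_eq_1))
  invisible(x)
}

#' Rensch's-rule verdict from an SMA slope confidence interval
#'
#' The verdict is read off the confidence interval's position relative to 1:
#' a lower limit above 1 supports Rensch's rule (dimorphism increases with
#' size in male-larger lineages), an upper limit below 1 supports its
#' converse, and an interval containing 1 supports isometry.
#'
#' @param fit An `sma_fit` object.
#' @return One of `"rensch_rule"`, `"converse"`, `"isometry"`.
#' @examples
#' classify_allometry(list(ci_low = 1.002, ci_high = 1.135)) # rensch_rule
#' @export
classify_allometry <- function(fit) {
  stopifnot(is.numeric(fit$ci_low), is.numeric(fit$ci_high),
            fit$ci_low <= fit$ci_high)
  if (fit$ci_low > 1) "rensch_rule"
  else if (fit$ci_high < 1) "converse"
  else "isometry"
}

#' Ordinary least-squares fit retaining the residual sum of squares
#'
#' Plain OLS of `y` on `x`, used for the sex-specific mass-length scaling
#' regressions. The residual sum of squares is retained because the Chow
#' test compares pooled against separate fits through their RSS.
#'
#' @param x,y Finite numeric vectors, `n >= 3`; `x` with nonzero variance.
#' @return An object of class `ols_fit`: list with `n`, `slope`,
#'   `intercept`, `r_squared`, `rss`.
#' @export
ols_fit <- function(x, y) {
  check_xy(x, y, min_n = 3)
  if (stats::sd(x) == 0)
    stop("degenerate input: zero variance in x", call. = FALSE)
  n <- length(x)
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(
    n = n,
    slope = slope,
    intercept = intercept,
    r_squared = if (tss == 0) 1 else max(0, min(1, 1 - rss / tss)),
    rss = rss
  ), class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit, n = %d: slope = %.4g, intercept = %.4g, r^2 = %.4g\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Chow test for a common regression across two groups
#'
#' Tests whether two groups share a single linear regression (intercept and
#' slope, k = 2 coefficients) against separate regressions:
#' `F = ((RSS_pooled - RSS_a - RSS_b) / k) / ((RSS_a + RSS_b) /
#' (n_a + n_b - 2k))`, referred to `F(k, n_a + n_b - 2k)`. Used to compare
#' male and female mass-length regressions.
#'
#' @param x_a,y_a First group's predictor and response (`n >= 3`).
#' @param x_b,y_b Second group's predictor and response (`n >= 3`).
#' @return List with `statistic` (F), `p_value`, `df1`, `df2`, and the
#'   three residual sums of squares.
#' @export
chow_test <- function(x_a, y_a, x_b, y_b) {
  fa <- ols_fit(x_a, y_a)
  fb <- ols_fit(x_b, y_b)
  fp <- ols_fit(c(x_a, x_b), c(y_a, y_b))
  k <- 2
  df2 <- fa$n + fb$n - 2 * k
  Fstat <- ((fp$rss - fa$rss - fb$rss) / k) / ((fa$rss + fb$rss) / df2)
  Fstat <- max(Fstat, 0)  # guard tiny negative round-off
  list(statistic = Fstat,
       p_value = stats::pf(Fstat, k, df2, lower.tail = FALSE),
       df1 = k, df2 = df2,
       rss_pooled = fp$rss, rss_a = fa$rss, rss_b = fb$rss)
}

#' Two-group OLS slope-equality t-test
#'
#' Tests whether two groups' OLS slopes differ:
#' `t = (b_a - b_b) / sqrt(se_a^2 + se_b^2)` on `n_a + n_b - 4` degrees of
#' freedom. Complements the Chow test, which is sensitive to intercept as
#' well as slope differences.
#'
#' @inheritParams chow_test
#' @return List with `statistic` (t), `p_value`, `df`, and the two slopes.
#' @export
slope_equality_test <- function(x_a, y_a, x_b, y_b) {
  fa <- ols_fit(x_a, y_a)
  fb <- ols_fit(x_b, y_b)
  se_of_slope <- function(fit, x) {
    sqrt(fit$rss / (fit$n - 2) / sum((x - mean(x))^2))
  }
  tstat <- (fa$slope - fb$slope) /
    sqrt(se_of_slope(fa, x_a)^2 + se_of_slope(fb, x_b)^2)
  df <- fa$n + fb$n - 4
  list(statistic = tstat,
       p_value = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
       df = df, slope_a = fa$slope, slope_b = fb$slope)
}

check_xy <- function(x, y, min_n) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  if (length(x) < min_n)
    stop("insufficient data: need at least ", min_n, " points",
         call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in input", call. = FALSE)
  invisible(TRUE)
}
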