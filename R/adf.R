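# Augmented Dickey-Fuller unit-root test (constant, no trend).
#
# Regression: diff(y)[t] = a + g*y[t-1] + sum_i b_i*diff(y)[t-i] + e[t].
# The test statistic is the t-ratio of g. P-values are interpolated from the
# classical quantile table of the tau_mu distribution (Fuller, 1976,
# Introduction to Statistical Time Series, Table 8.5.2), in both sample size
# and probability, and are therefore bounded to [0.01, 0.99].

ADF_TABLE_PROBS <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
ADF_TABLE_N <- c(25, 50, 100, 250, 500, Inf)
ADF_TABLE <- matrix(c(
  -3.75, -3.33, -3.00, -2.63, -0.37,  0.00,  0.34, 0.72,
  -3.58, -3.22, -2.93, -2.60, -0.40, -0.03,  0.29, 0.66,
  -3.51, -3.17, -2.89, -2.58, -0.42, -0.05,  0.26, 0.63,
  -3.46, -3.14, -2.88, -2.57, -0.42, -0.06,  0.24, 0.62,
  -3.44, -3.13, -2.87, -2.57, -0.43, -0.07,  0.24, 0.61,
  -3.43, -3.12, -2.86, -2.57, -0.44, -0.07,  0.23, 0.60),
  nrow = 6, byrow = TRUE)

adf_interp_pvalue <- function(tau, n_obs) {
  # interpolate the quantile table at this sample size, then invert
  quantiles <- vapply(seq_along(ADF_TABLE_PROBS), function(j) {
    stats::approx(1 / ADF_TABLE_N, ADF_TABLE[, j], xout = 1 / n_obs,
                  rule = 2)$y
  }, numeric(1))
  stats::approx(quantiles, ADF_TABLE_PROBS, xout = tau, rule = 2)$y
}

#' Augmented Dickey-Fuller test for a unit root
#'
#' Constant-only specification with a fixed lag order (default
#' `trunc((n - 1)^(1/3))`, a common deterministic rule). Small p-values
#' indicate a stationary series; interpolated p-values are truncated to
#' \[0.01, 0.99\].
#'
#' @param y Numeric series, length >= 10, non-constant.
#' @param lags Number of lagged differences in the regression.
#' @return List with `statistic` (tau), `p.value`, `lags`, `n_obs`.
#' @export
adf_test <- function(y, lags = trunc((length(y) - 1)^(1 / 3))) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 10) stop("series too short for the ADF regression")
  if (stats::sd(y) == 0) stop("ADF test is degenerate on a constant series")
  k <- as.integer(lags)
  stopifnot(k >= 0, n - k - 1 > k + 3)

  dy <- diff(y)
  m <- length(dy)
  idx <- (k + 1):m
  resp <- dy[idx]
  ylag <- y[idx]
  if (k > 0) {
    lagmat <- vapply(1:k, function(i) dy[idx - i], numeric(length(idx)))
    fit <- stats::lm(resp ~ ylag + lagmat)
  } else {
    fit <- stats::lm(resp ~ ylag)
  }
  ct <- stats::coef(summary(fit))
  if (!"ylag" %in% rownames(ct) || is.na(ct["ylag", "t value"])) {
    stop("ADF regression is degenerate (collinear lag term)")
  }
  tau <- unname(ct["ylag", "t value"])
  list(statistic = tau, p.value = adf_interp_pvalue(tau, length(resp)),
       lags = k, n_obs = length(resp))
}

#' ADF stationarity p-value of a smoothed trace
#'
#' Applies [adf_test()] to the valid (post-trim) range of a smoothed signal.
#' The resulting p-value is carried as a descriptive feature; by default it
#' is excluded from classifier input (see [feature_params()]).
#'
#' @param signal A [smoothed_signal()] with at least 30 valid values.
#' @return The ADF p-value.
#' @export
adf_pvalue <- function(signal) {
  stopifnot(inherits(signal, "smoothed_signal"))
  if (length(signal$values) < 30) {
    stop("valid range too short for the ADF stationarity feature (need >= 30)")
  }
  adf_test(signal$values)$p.value
}
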