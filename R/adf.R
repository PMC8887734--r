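# Augmented Dickey-Fuller unit-root test ---------------------------------

# Empirical percentiles of the Dickey-Fuller t-distribution (Fuller 1976;
# Banerjee et al. 1993), used for two-way interpolation of p-values.
.df_probs <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
.df_ns <- c(25, 50, 100, 250, 500, 1e5)
# with constant (drift), no trend
.df_tab_drift <- matrix(c(
  -3.75, -3.33, -3.00, -2.62, -0.37,  0.00,  0.34,  0.72,
  -3.58, -3.22, -2.93, -2.60, -0.40, -0.03,  0.29,  0.66,
  -3.51, -3.17, -2.89, -2.58, -0.42, -0.05,  0.26,  0.63,
  -3.46, -3.14, -2.88, -2.57, -0.42, -0.06,  0.24,  0.62,
  -3.44, -3.13, -2.87, -2.57, -0.43, -0.07,  0.24,  0.61,
  -3.43, -3.12, -2.86, -2.57, -0.44, -0.07,  0.23,  0.60), 6, 8, byrow = TRUE)
# with constant and linear trend
.df_tab_trend <- matrix(c(
  -4.38, -3.95, -3.60, -3.24, -1.14, -0.80, -0.50, -0.15,
  -4.15, -3.80, -3.50, -3.18, -1.19, -0.87, -0.58, -0.24,
  -4.04, -3.73, -3.45, -3.15, -1.22, -0.90, -0.62, -0.28,
  -3.99, -3.69, -3.43, -3.13, -1.23, -0.92, -0.64, -0.31,
  -3.98, -3.68, -3.42, -3.13, -1.24, -0.93, -0.65, -0.32,
  -3.96, -3.66, -3.41, -3.12, -1.25, -0.94, -0.66, -0.33), 6, 8, byrow = TRUE)

#' Augmented Dickey-Fuller test
#'
#' Tests the null hypothesis that the series has a unit root (is
#' nonstationary) against stationarity. The test regression is
#' `diff(y)[t] ~ y[t-1] + 1 (+ t) + lagged diffs`, with the number of lagged
#' differences chosen by AIC up to `max_lags` (default
#' `trunc((n - 1)^(1/3))`). P-values come from interpolating tabulated
#' percentiles of the Dickey-Fuller t-distribution; values beyond the table
#' are clamped to 0.01/0.99 with a warning.
#'
#' @param series numeric series, length >= 20.
#' @param type `"trend"` (constant + linear trend, the default) or `"drift"`
#'   (constant only).
#' @param max_lags maximum augmentation lag order.
#' @param lags fix the augmentation order instead of selecting it by AIC.
#' @return list with `statistic` (t-value on the lagged level), `p_value`,
#'   `lags` used, `type`, and `stationary` (reject unit root at 0.05).
#' @export
adf_test <- function(series, type = c("trend", "drift"), max_lags = NULL,
                     lags = NULL) {
  type <- match.arg(type)
  y <- as.numeric(series)
  n <- length(y)
  if (n < 20L) stop("series too short for a Dickey-Fuller test (need >= 20)")
  if (sd(y) == 0) stop("constant series: degenerate Dickey-Fuller regression")
  if (is.null(max_lags)) max_lags <- trunc((n - 1)^(1/3))
  if (!is.null(lags)) max_lags <- as.integer(lags)
  dy <- diff(y)
  fit_k <- function(k) {
    # common sample across candidate lag orders for a fair AIC comparison
    idx <- (max_lags + 1L):length(dy)
    X <- cbind(ylag = y[idx], intercept = 1)
    if (type == "trend") X <- cbind(X, trend = idx)
    if (k > 0L) {
      D <- sapply(seq_len(k), function(j) dy[idx - j])
      colnames(D) <- paste0("dlag", seq_len(k))
      X <- cbind(X, D)
    }
    fit <- lm.fit(X, dy[idx])
    rss <- sum(fit$residuals^2)
    nn <- length(idx)
    list(aic = nn * log(rss / nn) + 2 * ncol(X), fit = fit, X = X, n = nn)
  }
  if (!is.null(lags)) {
    k <- as.integer(lags)
    best <- fit_k(k)
  } else {
    fits <- lapply(0:max_lags, fit_k)
    k <- which.min(vapply(fits, `[[`, numeric(1), "aic")) - 1L
    best <- fits[[k + 1L]]
  }
  # t-statistic on the lagged level coefficient
  res <- best$fit$residuals
  sigma2 <- sum(res^2) / (best$n - ncol(best$X))
  XtXinv <- chol2inv(chol(crossprod(best$X)))
  se <- sqrt(sigma2 * XtXinv[1L, 1L])
  stat <- best$fit$coefficients[["ylag"]] / se
  tab <- if (type == "trend") .df_tab_trend else .df_tab_drift
  # interpolate percentiles over sample size, then p-value over the statistic
  row <- vapply(seq_along(.df_probs), function(j) {
    approx(.df_ns, tab[, j], xout = n, rule = 2)$y
  }, numeric(1))
  if (stat < min(row)) {
    warning("statistic below tabulated range; p-value clamped to 0.01")
    p <- 0.01
  } else if (stat > max(row)) {
    warning("statistic above tabulated range; p-value clamped to 0.99")
    p <- 0.99
  } else {
    p <- approx(row, .df_probs, xout = stat)$y
  }
  list(statistic = unname(stat), p_value = p, lags = k, type = type,
       stationary = p < 0.05)
}
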