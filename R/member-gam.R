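# Negative-binomial GAM member on raw counts -----------------------------

#' Fit the negative-binomial GAM member
#'
#' Counts are modelled as negative-binomial draws with a log link: the linear
#' predictor is an unpenalized cubic spline of time-in-years (nonlinear
#' trend), a cyclic cubic regression smooth of fortnight (period 24, endpoint
#' values matched) for seasonality, and a shrinkage-penalized smooth of each
#' lagged predictor so that uninformative predictors are selected out (their
#' effective degrees of freedom shrink to ~0). The overdispersion parameter
#' phi is estimated alongside; under this parameterization the variance is
#' `mu + mu^2 / phi`. Residual moving-average autocorrelation (two lags) is
#' estimated from deviance residuals and reported.
#'
#' @param counts a [fortnight_series()] of nonnegative integer admissions.
#' @param predictors a [select_lags()] set aligned to `counts`, or `NULL`.
#' @param k_trend,k_season basis dimensions for the trend and cyclic smooths.
#' @param k_pred basis dimension for each predictor's shrinkage smooth.
#' @return a `member_gam` fit: the `mgcv` fit, `phi`, per-smooth effective
#'   degrees of freedom, residual MA coefficients and residual sd.
#' @export
fit_gam_raw <- function(counts, predictors = NULL, k_trend = 8L,
                        k_season = 12L, k_pred = 5L) {
  y <- as.numeric(counts)
  if (any(y < 0) || any(y != round(y))) stop("counts must be nonnegative integers")
  if (all(y == 0)) stop("all-zero count series")
  n <- length(y)
  dat <- data.frame(count = y,
                    year_cont = seq_len(n) / 24,
                    fortnight = as.data.frame(counts)$fortnight)
  pnames <- character(0)
  if (!is.null(predictors)) {
    pnames <- colnames(predictors$x)
    for (nm in pnames) dat[[nm]] <- predictors$x[, nm]
  }
  smooths <- c(sprintf("s(year_cont, bs = 'cr', k = %d, fx = TRUE)", k_trend),
               sprintf("s(fortnight, bs = 'cc', k = %d)", k_season),
               sprintf("s(%s, bs = 'cs', k = %d)", pnames, k_pred))
  fml <- stats::as.formula(paste("count ~", paste(smooths, collapse = " + ")))
  fit <- mgcv::gam(fml, data = dat, family = mgcv::nb(), method = "REML",
                   knots = list(fortnight = c(0.5, 24.5)))
  phi <- fit$family$getTheta(TRUE)
  r <- residuals(fit, type = "deviance")
  ac <- acf(r, lag.max = 2L, plot = FALSE)$acf[2:3]
  edf_tab <- data.frame(term = vapply(fit$smooth, function(s) s$label,
                                      character(1)),
                        edf = vapply(seq_along(fit$smooth), function(i) {
                          s <- fit$smooth[[i]]
                          sum(fit$edf[s$first.para:s$last.para])
                        }, numeric(1)))
  structure(list(member = "gam_raw", target_scale = "raw_count",
                 fit = fit, phi = phi, edf = edf_tab,
                 resid_ma = ac, sigma = sd(r),
                 n = n, pnames = pnames,
                 counts = counts, candidates = predictors),
            class = c("member_gam", "tickcast_member"))
}

#' @describeIn fit_gam_raw simulate forecast sample paths (posterior draws of
#'   the linear predictor, then negative-binomial observation draws).
#' @param object fitted member.
#' @param horizon fortnights ahead.
#' @param n_paths sample trajectories.
#' @param seed optional integer seed.
#' @param persist_covariates carry covariates forward past their lag horizon.
#' @param ... unused.
#' @export
forecast.member_gam <- function(object, horizon, n_paths = 1000,
                                seed = NULL, persist_covariates = FALSE,
                                ...) {
  stopifnot(horizon >= 1)
  run <- function() {
    n <- object$n
    fn_last <- as.data.frame(object$counts)$fortnight[n]
    nd <- data.frame(year_cont = (n + seq_len(horizon)) / 24,
                     fortnight = ((fn_last + seq_len(horizon) - 1L) %% 24L) + 1L)
    if (length(object$pnames)) {
      xf <- future_xreg(object$candidates, horizon,
                        persist = persist_covariates, vars = object$pnames)
      for (nm in object$pnames) nd[[nm]] <- xf[, nm]
    }
    Xp <- predict(object$fit, newdata = nd, type = "lpmatrix")
    b <- coef(object$fit)
    V <- object$fit$Vp
    ch <- chol((V + t(V)) / 2 + diag(1e-10, length(b)))
    bs <- matrix(rnorm(n_paths * length(b)), n_paths) %*% ch
    bs <- sweep(bs, 2L, b, "+")
    eta <- bs %*% t(Xp)                      # n_paths x horizon
    mu <- exp(pmin(eta, 30))
    paths <- matrix(rnbinom(length(mu), mu = mu, size = object$phi),
                    n_paths, horizon)
    forecast_distribution(paths, origin = n, member = object$member,
                          scale = "count")
  }
  if (!is.null(seed)) with_seed(seed, run()) else run()
}
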