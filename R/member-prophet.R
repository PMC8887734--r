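# Decomposable piecewise-trend regression member (Prophet-style) ---------
#
# Gaussian model on log(count + 1): piecewise-linear trend whose slope
# changes at evenly spaced changepoints are shrunk by a sparse Laplace prior,
# Fourier-basis yearly seasonality with a Gaussian smoothing prior, and
# additive linear regressor terms. Fitting is by MAP (penalized least
# squares); forecast uncertainty combines observation noise with generative
# simulation of future trend changepoints, mirroring the historical
# changepoint frequency and magnitude.

prophet_bases <- function(tt, season_pos, changepoints, fourier_order) {
  A <- outer(tt, changepoints, function(t, s) pmax(t - s, 0))
  colnames(A) <- paste0("cp", seq_along(changepoints))
  F <- do.call(cbind, lapply(seq_len(fourier_order), function(k) {
    cbind(sin(2 * pi * k * season_pos), cos(2 * pi * k * season_pos))
  }))
  colnames(F) <- paste0(rep(c("sin", "cos"), fourier_order),
                        rep(seq_len(fourier_order), each = 2L))
  list(A = A, F = F)
}

#' Fit the piecewise-trend regression member on log1p counts
#'
#' The outcome is `log(count + 1)`. Regressors are chosen by testing each
#' candidate on its own against a trend + seasonality base model and keeping
#' the `n_predictors` with the lowest deviance. The trend changepoint prior
#' scale defaults to 0.50, allowing flexible nonlinear trends.
#'
#' @param counts a [fortnight_series()] of nonnegative counts.
#' @param predictors a [select_lags()] set aligned to `counts`, or `NULL`.
#' @param n_predictors regressors retained by the deviance ranking (all are
#'   used, with a warning, if fewer candidates exist).
#' @param changepoint_prior_scale Laplace prior scale on trend slope changes.
#' @param n_changepoints candidate changepoints, evenly spaced over the first
#'   80% of the series.
#' @param fourier_order harmonics of the yearly (24-fortnight) seasonality.
#' @return a `member_prophet` fit with MAP coefficients, changepoint
#'   magnitudes `delta`, selected regressors and residual sd.
#' @export
fit_prophet_raw <- function(counts, predictors = NULL, n_predictors = 3L,
                            changepoint_prior_scale = 0.50,
                            n_changepoints = 25L, fourier_order = 10L) {
  y <- as.numeric(counts)
  if (any(y < 0)) stop("counts must be nonnegative")
  z <- log1p(y)
  n <- length(z)
  tt <- seq_len(n) / n
  season_pos <- as.data.frame(counts)$fortnight / 24
  cps <- seq(0, 0.8, length.out = n_changepoints + 1L)[-1L]
  bases <- prophet_bases(tt, season_pos, cps, fourier_order)

  # deviance ranking of single regressors against the base model
  selected <- character(0)
  if (!is.null(predictors) && ncol(predictors$x) > 0L) {
    nms <- colnames(predictors$x)
    base_X <- cbind(1, tt, bases$F)
    dev1 <- vapply(nms, function(nm) {
      f <- lm.fit(cbind(base_X, predictors$x[, nm]), z)
      sum(f$residuals^2)
    }, numeric(1))
    if (length(nms) < n_predictors) {
      warning("fewer candidate predictors than n_predictors; using all")
    }
    selected <- names(sort(dev1))[seq_len(min(n_predictors, length(nms)))]
  }
  Xr <- if (length(selected)) predictors$x[, selected, drop = FALSE] else
    matrix(0, n, 0L)

  X <- cbind(intercept = 1, slope = tt, bases$A, bases$F, Xr)
  idx_cp <- 2L + seq_len(ncol(bases$A))
  idx_seas <- max(idx_cp) + seq_len(ncol(bases$F))
  idx_reg <- if (ncol(Xr)) max(idx_seas) + seq_len(ncol(Xr)) else integer(0)

  sigma <- sd(lm.fit(cbind(1, tt, bases$F), z)$residuals) + 1e-6
  tau <- changepoint_prior_scale
  theta <- rep(0, ncol(X)); theta[1L] <- mean(z)
  for (pass in 1:2) {
    obj <- function(th) {
      r <- z - as.numeric(X %*% th)
      sum(r^2) / (2 * sigma^2) +
        sum(sqrt(th[idx_cp]^2 + 1e-10)) / tau +
        sum(th[idx_seas]^2) / (2 * 100) +
        (if (length(idx_reg)) sum(th[idx_reg]^2) / (2 * 100) else 0)
    }
    grad <- function(th) {
      r <- z - as.numeric(X %*% th)
      g <- -as.numeric(crossprod(X, r)) / sigma^2
      g[idx_cp] <- g[idx_cp] + th[idx_cp] / sqrt(th[idx_cp]^2 + 1e-10) / tau
      g[idx_seas] <- g[idx_seas] + th[idx_seas] / 100
      if (length(idx_reg)) g[idx_reg] <- g[idx_reg] + th[idx_reg] / 100
      g
    }
    op <- optim(theta, obj, grad, method = "BFGS",
                control = list(maxit = 500))
    theta <- op$par
    sigma <- sqrt(mean((z - as.numeric(X %*% theta))^2)) + 1e-8
  }

  delta <- theta[idx_cp]
  coef_tab <- if (length(selected)) {
    data.frame(term = selected, estimate = theta[idx_reg])
  } else NULL
  structure(list(member = "prophet_raw", target_scale = "log1p_count",
                 theta = theta, delta = delta,
                 idx = list(cp = idx_cp, seas = idx_seas, reg = idx_reg),
                 changepoints = cps, fourier_order = fourier_order,
                 selected = selected, coefficients = coef_tab,
                 sigma = sigma, n = n,
                 season_last = as.data.frame(counts)$fortnight[n],
                 cp_rate = n_changepoints / n,
                 tau_hat = mean(abs(delta)),
                 counts = counts, candidates = predictors),
            class = c("member_prophet", "tickcast_member"))
}

#' @describeIn fit_prophet_raw simulate forecast sample paths; paths are
#'   back-transformed with `exp(.) - 1` and truncated at zero.
#' @param object fitted member.
#' @param horizon fortnights ahead.
#' @param n_paths sample trajectories.
#' @param seed optional integer seed.
#' @param persist_covariates carry covariates forward past their lag horizon.
#' @param ... unused.
#' @export
forecast.member_prophet <- function(object, horizon, n_paths = 1000,
                                    seed = NULL, persist_covariates = FALSE,
                                    ...) {
  stopifnot(horizon >= 1)
  run <- function() {
    n <- object$n
    tt <- (n + seq_len(horizon)) / n
    season_pos <- (((object$season_last + seq_len(horizon) - 1L) %% 24L) + 1L) / 24
    bases <- prophet_bases(tt, season_pos, object$changepoints,
                           object$fourier_order)
    Xr <- if (length(object$selected)) {
      xf <- future_xreg(object$candidates, horizon,
                        persist = persist_covariates, vars = object$selected)
      xf[, object$selected, drop = FALSE]
    } else matrix(0, horizon, 0L)
    X <- cbind(1, tt, bases$A, bases$F, Xr)
    mean_path <- as.numeric(X %*% object$theta)
    # generative future-trend uncertainty: new changepoints arrive at the
    # historical rate with Laplace-distributed slope changes
    paths <- matrix(rep(mean_path, each = n_paths), n_paths, horizon)
    if (object$tau_hat > 1e-8) {
      dt <- 1 / n
      for (i in seq_len(n_paths)) {
        hit <- runif(horizon) < object$cp_rate
        if (any(hit)) {
          # Laplace draw: difference of exponentials
          dlt <- ifelse(hit,
                        rexp(horizon, 1 / object$tau_hat) -
                          rexp(horizon, 1 / object$tau_hat), 0)
          slope_extra <- cumsum(dlt)
          paths[i, ] <- paths[i, ] + cumsum(slope_extra * dt)
        }
      }
    }
    paths <- paths + matrix(rnorm(n_paths * horizon, 0, object$sigma),
                            n_paths, horizon)
    paths <- pmax(expm1(paths), 0)
    forecast_distribution(paths, origin = n, member = object$member,
                          scale = "count")
  }
  if (!is.null(seed)) with_seed(seed, run()) else run()
}
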