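# Additive exponential smoothing state-space models ----------------------
#
# Compact innovations state-space implementation covering the additive-error
# family ANN / AAN / ANA / AAA (error, trend, seasonal), with smoothing
# parameters and initial level/trend estimated by Gaussian likelihood and the
# component structure chosen by AIC.

ets_filter <- function(y, m, alpha, beta, gamma, l0, b0, s0,
                       trendtype, seasontype) {
  n <- length(y)
  l <- l0; b <- b0
  s <- if (seasontype == "A") s0 else numeric(0)
  e <- numeric(n)
  fitted <- numeric(n)
  for (t in seq_len(n)) {
    seas <- if (seasontype == "A") s[1L] else 0
    mu <- l + (if (trendtype == "A") b else 0) + seas
    fitted[t] <- mu
    e[t] <- y[t] - mu
    lnew <- l + (if (trendtype == "A") b else 0) + alpha * e[t]
    if (trendtype == "A") b <- b + beta * e[t]
    if (seasontype == "A") s <- c(s[-1L], s[1L] + gamma * e[t])
    l <- lnew
  }
  list(e = e, fitted = fitted, l = l, b = b, s = s)
}

ets_init_states <- function(y, m, trendtype, seasontype) {
  n <- length(y)
  if (seasontype == "A" && n >= 2L * m) {
    # classical decomposition on the first cycles for seasonal initials
    ncyc <- min(5L, n %/% m)
    yy <- y[seq_len(ncyc * m)]
    trend_est <- stats::filter(yy, rep(1 / m, m), sides = 2)
    detr <- yy - trend_est
    s0 <- tapply(detr, rep_len(seq_len(m), length(yy)), mean, na.rm = TRUE)
    s0 <- as.numeric(s0) - mean(as.numeric(s0))
    deseas <- y[seq_len(min(2L * m, n))] -
      rep_len(s0, min(2L * m, n))
  } else {
    s0 <- rep(0, m)
    deseas <- y[seq_len(min(2L * max(m, 5L), n))]
  }
  tt <- seq_along(deseas)
  cf <- coef(lm(deseas ~ tt))
  l0 <- unname(cf[1L])
  b0 <- if (trendtype == "A") unname(cf[2L]) else 0
  list(l0 = l0, b0 = b0, s0 = s0)
}

ets_fit_one <- function(y, m, trendtype, seasontype) {
  init <- ets_init_states(y, m, trendtype, seasontype)
  obj <- function(p) {
    alpha <- p[1L]
    beta <- if (trendtype == "A") p[2L] else 0
    gamma <- if (seasontype == "A") p[length(p) - 2L] else 0
    l0 <- p[length(p) - 1L]; b0 <- p[length(p)]
    if (beta > alpha || gamma > 1 - alpha) return(1e12)
    f <- ets_filter(y, m, alpha, beta, gamma, l0, init$b0 + b0,
                    init$s0, trendtype, seasontype)
    sum(f$e^2)
  }
  p0 <- c(0.2,
          if (trendtype == "A") 0.05,
          if (seasontype == "A") 0.05,
          init$l0, 0)
  lower <- c(1e-4, if (trendtype == "A") 0, if (seasontype == "A") 0,
             init$l0 - 3 * (sd(y) + 1e-8), -abs(init$b0) - sd(y) / 10 - 1e-6)
  upper <- c(0.9999, if (trendtype == "A") 0.9999,
             if (seasontype == "A") 0.9999,
             init$l0 + 3 * (sd(y) + 1e-8), abs(init$b0) + sd(y) / 10 + 1e-6)
  op <- optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper)
  p <- op$par
  alpha <- p[1L]
  beta <- if (trendtype == "A") p[2L] else 0
  gamma <- if (seasontype == "A") p[length(p) - 2L] else 0
  f <- ets_filter(y, m, alpha, beta, gamma, p[length(p) - 1L],
                  init$b0 + p[length(p)], init$s0, trendtype, seasontype)
  n <- length(y)
  sse <- max(sum(f$e^2), 1e-12)
  k <- 2L + (trendtype == "A") * 2L +
    (seasontype == "A") * (1L + m) + 1L  # params + initials + sigma
  aic <- n * log(sse / n) + 2 * k
  list(model = paste0("A", trendtype, seasontype),
       alpha = alpha, beta = beta, gamma = gamma,
       states = list(l = f$l, b = f$b, s = f$s),
       sigma = sqrt(sse / n), aic = aic,
       fitted = f$fitted, residuals = f$e,
       trendtype = trendtype, seasontype = seasontype, m = m, n = n)
}

#' Fit an additive exponential smoothing model with automatic components
#'
#' Error is additive; trend (none/additive) and seasonality (none/additive)
#' are chosen by AIC over the candidate structures. Smoothing parameters and
#' initial level/trend are estimated by maximizing the Gaussian one-step
#' likelihood; initial seasonal states come from a classical decomposition of
#' the early cycles.
#'
#' @param y numeric series.
#' @param m seasonal period (24 for fortnightly data).
#' @param model `"auto"` or one of `"ANN"`, `"AAN"`, `"ANA"`, `"AAA"`.
#' @return an `ets_model` list with smoothing parameters, final states,
#'   innovation `sigma`, `aic`, fitted values and residuals.
#' @export
ets_fit <- function(y, m = 24L, model = "auto") {
  y <- as.numeric(y)
  cands <- if (identical(model, "auto")) {
    if (length(y) >= 2L * m + 4L) {
      list(c("N", "N"), c("A", "N"), c("N", "A"), c("A", "A"))
    } else {
      list(c("N", "N"), c("A", "N"))
    }
  } else {
    list(c(substr(model, 2, 2), substr(model, 3, 3)))
  }
  fits <- lapply(cands, function(ts_) {
    tryCatch(ets_fit_one(y, m, ts_[1L], ts_[2L]), error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) stop("all exponential smoothing candidates failed")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "aic"))]]
  class(best) <- "ets_model"
  best
}

# Simulate sample paths from a fitted ETS model
ets_simulate <- function(fit, horizon, n_paths = 1000) {
  paths <- matrix(0, n_paths, horizon)
  for (i in seq_len(n_paths)) {
    l <- fit$states$l; b <- fit$states$b; s <- fit$states$s
    for (h in seq_len(horizon)) {
      seas <- if (fit$seasontype == "A") s[1L] else 0
      mu <- l + (if (fit$trendtype == "A") b else 0) + seas
      e <- rnorm(1L, 0, fit$sigma)
      paths[i, h] <- mu + e
      lnew <- l + (if (fit$trendtype == "A") b else 0) + fit$alpha * e
      if (fit$trendtype == "A") b <- b + fit$beta * e
      if (fit$seasontype == "A") s <- c(s[-1L], s[1L] + fit$gamma * e)
      l <- lnew
    }
  }
  paths
}

# Point (mean) forecast from a fitted ETS model
ets_mean_forecast <- function(fit, horizon) {
  l <- fit$states$l; b <- fit$states$b; s <- fit$states$s
  out <- numeric(horizon)
  for (h in seq_len(horizon)) {
    seas <- if (fit$seasontype == "A") {
      s[((h - 1L) %% length(s)) + 1L]
    } else 0
    out[h] <- l + (if (fit$trendtype == "A") h * b else 0) + seas
  }
  out
}
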