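# Bayesian heteroskedastic moving-average regression member --------------
#
# Mean: intercept + MA(2) on past innovations + linear predictor effects.
# Conditional variance: ARCH-type with two moving-average volatility lags,
# sigma2[t] = a0 + a1*eps[t-1]^2 + a2*eps[t-2]^2, so both the mean and the
# variance are influenced by two moving-average lags. Regression coefficients
# get regularizing double-exponential (Laplace) priors with mean 0 and sd
# 0.5; estimation is by Gibbs sampling (JAGS).

garch_model_string <- "
model {
  eps[1] <- y[1] - b0
  eps[2] <- y[2] - b0
  for (t in 3:T) {
    m[t] <- b0 + xb[t] + th1 * eps[t-1] + th2 * eps[t-2]
    eps[t] <- y[t] - m[t]
    s2[t] <- a0 + a1 * pow(eps[t-1], 2) + a2 * pow(eps[t-2], 2)
    y[t] ~ dnorm(m[t], 1 / s2[t])
  }
  for (t in 1:T) { xb[t] <- inprod(X[t, ], beta) }
  b0 ~ dnorm(0, 0.01)
  th1 ~ dnorm(0, 1)
  th2 ~ dnorm(0, 1)
  for (j in 1:P) { beta[j] ~ ddexp(0, 2.8284271) }  # Laplace, sd = 0.5
  a0 ~ dgamma(1, 1)
  a1 ~ dbeta(1, 3)
  a2 ~ dbeta(1, 3)
}"

#' Fit the Bayesian heteroskedastic MA(2) regression member
#'
#' All predictors enter simultaneously with Laplace(0, sd 0.5) shrinkage
#' priors; no subset search. Four chains are run and pooled, thinned to
#' `n_keep` retained posterior draws. Convergence is summarized by the
#' largest split R-hat; fits with R-hat >= 1.05 are flagged not converged and
#' should be excluded from the ensemble.
#'
#' @param target seasonally adjusted training series.
#' @param predictors a [select_lags()] set aligned to `target` (may be
#'   `NULL` for an intercept + MA(2) model).
#' @param chains,n_iter,n_adapt,n_burn MCMC settings (defaults: 4 chains of
#'   1000 draws each after adaptation/burn-in).
#' @param n_keep posterior draws retained after pooling (default 1000).
#' @param quiet suppress JAGS progress output.
#' @return a `member_garch` fit: pooled posterior draw matrix, per-draw
#'   terminal innovations, coefficient summaries, `rhat_max`, `converged`.
#' @export
fit_garch_seasadj <- function(target, predictors = NULL, chains = 4L,
                              n_iter = 1000L, n_adapt = 500L, n_burn = 500L,
                              n_keep = 1000L, quiet = TRUE) {
  y <- as.numeric(target)
  if (any(!is.finite(y))) stop("target contains non-finite values")
  X <- if (!is.null(predictors)) predictors$x else matrix(0, length(y), 1L)
  has_x <- !is.null(predictors)
  P <- ncol(X)
  jm <- rjags::jags.model(textConnection(garch_model_string),
                          data = list(y = y, X = X, T = length(y), P = P),
                          n.chains = chains, n.adapt = n_adapt,
                          quiet = quiet)
  update(jm, n_burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("b0", "th1", "th2", "beta",
                                    "a0", "a1", "a2"),
                              n.iter = n_iter, progress.bar = "none")
  rhat <- tryCatch({
    g <- coda::gelman.diag(samp, autoburnin = FALSE, multivariate = FALSE)
    max(g$psrf[, 1L], na.rm = TRUE)
  }, error = function(e) NA_real_)
  pooled <- as.matrix(do.call(rbind, lapply(samp, as.matrix)))
  keep <- seq(1L, nrow(pooled),
              length.out = min(n_keep, nrow(pooled)))
  draws <- pooled[round(keep), , drop = FALSE]
  bnames <- if (has_x) colnames(predictors$x) else character(0)
  beta_cols <- grep("^beta", colnames(draws))
  # per-draw terminal innovations (deterministic given parameters and data)
  eps_tail <- garch_eps_tail(draws, y, X, beta_cols)
  qs <- function(v) c(mean(v), quantile(v, c(0.025, 0.975)))
  coef_tab <- NULL
  if (has_x) {
    cs <- t(apply(draws[, beta_cols, drop = FALSE], 2L, qs))
    coef_tab <- data.frame(term = bnames, estimate = cs[, 1L],
                           lo95 = cs[, 2L], up95 = cs[, 3L])
  }
  structure(list(member = "garch_seasadj",
                 target_scale = "seasonally_adjusted",
                 draws = draws, beta_cols = beta_cols,
                 eps_tail = eps_tail, bnames = bnames,
                 coefficients = coef_tab,
                 rhat_max = rhat,
                 converged = is.finite(rhat) && rhat < 1.05,
                 sigma = sd(garch_residual_mean(draws, y, X, beta_cols)),
                 y = y, candidates = predictors),
            class = c("member_garch", "tickcast_member"))
}

# Recompute the innovation series for each posterior draw (vectorized over
# draws, stepping through time) and return the last two innovations.
garch_eps_tail <- function(draws, y, X, beta_cols) {
  nd <- nrow(draws)
  Tn <- length(y)
  b0 <- draws[, "b0"]; th1 <- draws[, "th1"]; th2 <- draws[, "th2"]
  XB <- X %*% t(draws[, beta_cols, drop = FALSE])  # T x nd
  e1 <- y[1L] - b0   # eps[t-1] entering step t
  e2 <- y[2L] - b0
  prev2 <- e1; prev1 <- e2
  for (t in 3:Tn) {
    m <- b0 + XB[t, ] + th1 * prev1 + th2 * prev2
    e <- y[t] - m
    prev2 <- prev1; prev1 <- e
  }
  cbind(eps1 = prev1, eps2 = prev2)  # most recent first
}

# Posterior-mean one-step residuals (for an overall residual scale)
garch_residual_mean <- function(draws, y, X, beta_cols) {
  cm <- colMeans(draws)
  b0 <- cm[["b0"]]; th1 <- cm[["th1"]]; th2 <- cm[["th2"]]
  xb <- as.numeric(X %*% cm[beta_cols])
  Tn <- length(y)
  eps <- numeric(Tn)
  eps[1L] <- y[1L] - b0; eps[2L] <- y[2L] - b0
  for (t in 3:Tn) {
    m <- b0 + xb[t] + th1 * eps[t - 1L] + th2 * eps[t - 2L]
    eps[t] <- y[t] - m
  }
  eps
}

# Simulation state: each trajectory carries one posterior draw and its two
# most recent innovations.
garch_state_init <- function(object, n) {
  idx <- sample.int(nrow(object$draws), n, replace = TRUE)
  d <- object$draws[idx, , drop = FALSE]
  et <- object$eps_tail[idx, , drop = FALSE]
  list(kind = "garch", n = n,
       b0 = d[, "b0"], th1 = d[, "th1"], th2 = d[, "th2"],
       a0 = d[, "a0"], a1 = d[, "a1"], a2 = d[, "a2"],
       B = d[, object$beta_cols, drop = FALSE],
       bnames = object$bnames,
       eps1 = et[, "eps1"], eps2 = et[, "eps2"])
}

garch_state_step <- function(state, xrow = NULL, innov_z = NULL) {
  n <- state$n
  s2 <- state$a0 + state$a1 * state$eps1^2 + state$a2 * state$eps2^2
  m <- state$b0 + state$th1 * state$eps1 + state$th2 * state$eps2
  if (length(state$bnames)) {
    xr <- xrow[state$bnames]
    if (anyNA(xr)) stop("missing regressor values for: ",
                        paste(state$bnames[is.na(xr)], collapse = ", "))
    m <- m + as.numeric(state$B %*% xr)
  }
  if (is.null(innov_z)) innov_z <- rnorm(n)
  eps_new <- innov_z * sqrt(s2)
  values <- m + eps_new
  state$eps2 <- state$eps1
  state$eps1 <- eps_new
  list(state = state, values = values)
}

#' @describeIn fit_garch_seasadj simulate posterior-predictive sample paths.
#' @param object fitted member.
#' @param horizon fortnights ahead.
#' @param n_paths sample trajectories.
#' @param seed optional integer seed.
#' @param persist_covariates carry covariates forward past their lag horizon.
#' @param ... unused.
#' @export
forecast.member_garch <- function(object, horizon, n_paths = 1000,
                                  seed = NULL, persist_covariates = FALSE,
                                  ...) {
  stopifnot(horizon >= 1)
  run <- function() {
    xf <- if (length(object$bnames)) {
      future_xreg(object$candidates, horizon, persist = persist_covariates,
                  vars = object$bnames)
    } else NULL
    state <- garch_state_init(object, n_paths)
    paths <- matrix(0, n_paths, horizon)
    for (h in seq_len(horizon)) {
      st <- garch_state_step(state, xrow = if (!is.null(xf)) xf[h, ] else NULL)
      state <- st$state
      paths[, h] <- st$values
    }
    forecast_distribution(paths, origin = length(object$y),
                          member = object$member,
                          scale = "seasonally_adjusted")
  }
  if (!is.null(seed)) with_seed(seed, run()) else run()
}
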