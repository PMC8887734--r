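# Sequential Monte Carlo assimilation of incoming observations -----------

#' Particle filter configuration
#'
#' @param obs_noise_sd observation likelihood scale; defaults (at
#'   [init_particles()]) to the member fit's residual sd.
#' @param mutation_sd Gaussian random-walk jitter added to resampled
#'   trajectory states; defaults to 10% of `obs_noise_sd`.
#' @param ess_threshold_fraction resample when the effective sample size
#'   falls below this fraction of N (default 0.5, i.e. N/2).
#' @param resample_method `"multinomial"` (resampling with replacement in
#'   proportion to weights) or `"systematic"`.
#' @return a `filter_config` list.
#' @export
filter_config <- function(obs_noise_sd = NULL, mutation_sd = NULL,
                          ess_threshold_fraction = 0.5,
                          resample_method = c("multinomial", "systematic")) {
  resample_method <- match.arg(resample_method)
  stopifnot(is.null(obs_noise_sd) || obs_noise_sd > 0,
            is.null(mutation_sd) || mutation_sd >= 0,
            ess_threshold_fraction > 0, ess_threshold_fraction <= 1)
  structure(list(obs_noise_sd = obs_noise_sd, mutation_sd = mutation_sd,
                 ess_threshold_fraction = ess_threshold_fraction,
                 resample_method = resample_method),
            class = "filter_config")
}

member_state_init <- function(fit, n) {
  if (inherits(fit, "member_arima")) return(arima_state_init(fit, n))
  if (inherits(fit, "member_garch")) return(garch_state_init(fit, n))
  stop("particle filtering supports the seasonally adjusted members ",
       "(regression-ARIMA and the heteroskedastic MA regression) only")
}

member_state_step <- function(state, xrow = NULL) {
  switch(state$kind,
         arima = arima_state_step(state, xrow),
         garch = garch_state_step(state, xrow),
         stop("unknown particle state kind"))
}

state_reindex <- function(state, idx) {
  for (nm in names(state)) {
    v <- state[[nm]]
    if (is.matrix(v) && nrow(v) == state$n) state[[nm]] <- v[idx, , drop = FALSE]
    else if (is.numeric(v) && length(v) == state$n && !nm %in% c("n")) {
      state[[nm]] <- v[idx]
    }
  }
  state
}

state_mutate <- function(state, sd) {
  if (sd <= 0) return(state)
  jit <- rnorm(state$n, 0, sd)
  if (state$kind == "arima") {
    pp <- state$parts
    if (pp$d > 0L) state$Z[, 1L] <- state$Z[, 1L] + jit
    else if (pp$p > 0L) state$W[, 1L] <- state$W[, 1L] + jit
    else if (pp$q > 0L) state$E[, 1L] <- state$E[, 1L] + jit
  } else if (state$kind == "garch") {
    state$eps1 <- state$eps1 + jit
  }
  state
}

#' Initialize a particle set from a fitted seasonally adjusted member
#'
#' Draws `n` forecast trajectories from the fitted model's simulation
#' (posterior draws for the Bayesian member, innovation simulation plus
#' coefficient draws for the ARIMA member) with uniform weights.
#'
#' @param fit a `member_arima` or `member_garch` fit.
#' @param n particle count (default 5000).
#' @param cfg a [filter_config()].
#' @param covariates optional covariate table extending the member's
#'   training table (same grid); needed so regressor rows can be built while
#'   observations keep arriving.
#' @param t_offset time offset (fortnights, relative to the end of the
#'   member's training window) at which assimilation starts; negative values
#'   start inside the training period (clinic-level reuse).
#' @param init_state `"fit"` starts trajectories from the fitted terminal
#'   state; `"level"` resets the trajectory level to `init_level` (used with
#'   negative `t_offset`).
#' @param init_level trajectory level for `init_state = "level"`.
#' @param seed optional integer seed.
#' @return a `particle_set`.
#' @export
init_particles <- function(fit, n = 5000L, cfg = filter_config(),
                           covariates = NULL, t_offset = 0L,
                           init_state = c("fit", "level"), init_level = 0,
                           seed = NULL) {
  init_state <- match.arg(init_state)
  build <- function() {
    state <- member_state_init(fit, n)
    if (init_state == "level") {
      if (state$kind == "arima") {
        if (ncol(state$W)) state$W[] <- 0
        if (ncol(state$E)) state$E[] <- 0
        if (ncol(state$Z)) {
          state$Z[] <- 0
          state$Z[, 1L] <- init_level
        }
      } else {
        state$eps1 <- rep(0, n); state$eps2 <- rep(0, n)
      }
    }
    if (is.null(cfg$obs_noise_sd)) cfg$obs_noise_sd <- fit$sigma
    if (is.null(cfg$mutation_sd)) cfg$mutation_sd <- 0.1 * cfg$obs_noise_sd
    structure(list(n = n, member = fit$member, fit = fit, state = state,
                   log_w = rep(0, n), cfg = cfg,
                   covariates = covariates, t = as.integer(t_offset),
                   values = NULL),
              class = "particle_set")
  }
  if (!is.null(seed)) with_seed(seed, build()) else build()
}

#' Normalized particle weights
#'
#' Accumulated log-weights (condensation is performed in log space to avoid
#' underflow) converted to normalized weights summing to one.
#' @param particles a `particle_set`.
#' @return numeric vector of length N.
#' @export
particle_weights <- function(particles) {
  lw <- particles$log_w
  if (all(!is.finite(lw))) stop("all particle weights are zero")
  w <- exp(lw - max(lw[is.finite(lw)]))
  w[!is.finite(w)] <- 0
  w / sum(w)
}

#' Current particle trajectory values
#'
#' The most recent proposed observation value of each particle (available
#' after the first [assimilate()] step).
#' @param particles a `particle_set`.
#' @return numeric vector of length N, or `NULL` before any step.
#' @export
particle_values <- function(particles) particles$values

member_vars <- function(fit) {
  if (inherits(fit, "member_arima")) fit$selected else fit$bnames
}

member_xrow <- function(ps, horizon = 1L) {
  vars <- member_vars(ps$fit)
  if (!length(vars)) return(NULL)
  lp <- ps$fit$candidates
  cov <- if (!is.null(ps$covariates)) ps$covariates else lp$covariates
  future_xreg(lp, horizon, covariates = cov, offset = ps$t, vars = vars)
}

#' Assimilate one observation into a particle set
#'
#' Each particle proposes the next value by propagating its trajectory one
#' step through the member's model equations; the Gaussian log-likelihood of
#' the observation given the proposal (scale `obs_noise_sd`) is added to the
#' particle's accumulated log-weight (condensation), and weights are
#' renormalized on demand. Resampling is a separate step
#' ([maybe_resample()]).
#'
#' @param particles a `particle_set`.
#' @param observation the next observed value on the member's (seasonally
#'   adjusted) scale.
#' @return the updated `particle_set`, advanced one step.
#' @export
assimilate <- function(particles, observation) {
  if (!is.finite(observation)) stop("observation must be finite")
  xr <- member_xrow(particles, 1L)
  st <- member_state_step(particles$state,
                          xrow = if (!is.null(xr)) xr[1L, ] else NULL)
  particles$state <- st$state
  particles$values <- st$values
  particles$log_w <- particles$log_w +
    dnorm(observation, st$values, particles$cfg$obs_noise_sd, log = TRUE)
  particles$t <- particles$t + 1L
  particles
}

#' Effective sample size of a particle set
#'
#' `1 / sum(w^2)` for normalized weights `w`; equals N for uniform weights
#' and 1 when a single particle carries all the weight.
#' @param particles a `particle_set` (or a bare numeric weight vector).
#' @return scalar in `[1, N]`.
#' @export
effective_sample_size <- function(particles) {
  w <- if (inherits(particles, "particle_set")) particle_weights(particles)
  else {
    if (sum(particles) == 0) stop("all particle weights are zero")
    particles / sum(particles)
  }
  1 / sum(w^2)
}

resample_indices <- function(w, n, method) {
  if (method == "multinomial") {
    sample.int(n, n, replace = TRUE, prob = w)
  } else {
    u <- (runif(1L) + seq_len(n) - 1L) / n
    findInterval(u, cumsum(w)) + 1L
  }
}

#' Resample and mutate when weights degenerate
#'
#' If the effective sample size falls below `N * ess_threshold_fraction`
#' (default N/2), particles are resampled with replacement in proportion to
#' their weights, a Gaussian random-walk jitter of scale `mutation_sd` is
#' added to each resampled trajectory state to restore diversity, and
#' weights are reset to uniform. Otherwise the set is returned unchanged.
#'
#' @param particles a `particle_set`.
#' @return a `particle_set`.
#' @export
maybe_resample <- function(particles) {
  n <- particles$n
  if (effective_sample_size(particles) >= n * particles$cfg$ess_threshold_fraction) {
    return(particles)
  }
  w <- particle_weights(particles)
  idx <- resample_indices(w, n, particles$cfg$resample_method)
  particles$state <- state_reindex(particles$state, idx)
  if (!is.null(particles$values)) particles$values <- particles$values[idx]
  particles$state <- state_mutate(particles$state, particles$cfg$mutation_sd)
  particles$log_w <- rep(0, n)
  particles
}

#' Forecast from the current particle set
#'
#' Propagates the weighted particles over the horizon through the member's
#' model equations; quantiles are computed with the particle weights. When a
#' seasonal forecast is supplied the paths are moved to the count scale as in
#' [to_outcome_scale()] (pathwise addition, truncation at zero).
#'
#' @param particles a `particle_set`.
#' @param horizon fortnights ahead (>= 1).
#' @param ets_seasonal_forecast optional seasonal-component
#'   [forecast_distribution()] over the same horizons.
#' @param persist_covariates carry covariates forward past their lag horizon.
#' @param seed optional integer seed.
#' @return a weighted [forecast_distribution()].
#' @export
pf_forecast <- function(particles, horizon, ets_seasonal_forecast = NULL,
                        persist_covariates = FALSE, seed = NULL) {
  if (horizon < 1) stop("horizon must be >= 1")
  run <- function() {
    fit <- particles$fit
    vars <- member_vars(fit)
    xf <- if (length(vars)) {
      lp <- fit$candidates
      cov <- if (!is.null(particles$covariates)) particles$covariates else
        lp$covariates
      future_xreg(lp, horizon, covariates = cov, offset = particles$t,
                  persist = persist_covariates, vars = vars)
    } else NULL
    state <- particles$state
    paths <- matrix(0, particles$n, horizon)
    for (h in seq_len(horizon)) {
      st <- member_state_step(state, xrow = if (!is.null(xf)) xf[h, ] else NULL)
      state <- st$state
      paths[, h] <- st$values
    }
    fc <- forecast_distribution(paths, origin = particles$t,
                                member = paste0(particles$member, "_pf"),
                                scale = "seasonally_adjusted",
                                weights = particle_weights(particles))
    if (!is.null(ets_seasonal_forecast)) {
      fc <- to_outcome_scale(fc, ets_seasonal_forecast)
    }
    fc
  }
  if (!is.null(seed)) with_seed(seed, run()) else run()
}

#' Adapt aggregate-level fits to clinic-level series
#'
#' Reuses the parameter distributions of the aggregate seasonally adjusted
#' member fits for each clinic, re-initializing only the Gaussian
#' observation-error scale per clinic from the residual sd of an
#' ARIMA(1,0,1) fit to that clinic's seasonally adjusted series, then runs
#' assimilation (with resampling) over the clinic series from its start.
#'
#' @param fits named list of aggregate `member_arima` / `member_garch` fits.
#' @param clinic_series named list of clinic-level [fortnight_series()]
#'   counts on the same fortnight grid as the aggregate training series.
#' @param n particles per filter.
#' @param cfg base [filter_config()]; `obs_noise_sd` is overridden per
#'   clinic.
#' @param covariates optional covariate table extension (see
#'   [init_particles()]).
#' @param seed integer seed.
#' @return per-clinic list: `particles` (per member), `obs_noise_sd`,
#'   `seasadj` (the clinic's seasonally adjusted series).
#' @export
adapt_to_subseries <- function(fits, clinic_series, n = 5000L,
                               cfg = filter_config(), covariates = NULL,
                               seed = 1L) {
  out <- list()
  for (cl in names(clinic_series)) {
    ser <- clinic_series[[cl]]
    if (length(ser) < 48L) {
      stop("clinic series '", cl, "' shorter than two seasonal cycles")
    }
    sa <- seasonally_adjust(stl_decompose(ser))
    a101 <- try_arima(as.numeric(sa), c(1L, 0L, 1L))
    if (is.null(a101)) stop("ARIMA(1,0,1) error fit failed for clinic ", cl)
    obs_sd <- sqrt(a101$sigma2)
    ccfg <- cfg
    ccfg$obs_noise_sd <- obs_sd
    if (is.null(ccfg$mutation_sd)) ccfg$mutation_sd <- 0.1 * obs_sd
    filters <- list()
    for (m in names(fits)) {
      ps <- init_particles(fits[[m]], n = n, cfg = ccfg,
                           covariates = covariates,
                           t_offset = -length(sa),
                           init_state = "level",
                           init_level = mean(as.numeric(sa)[1:24]),
                           seed = seed)
      for (obs in as.numeric(sa)) {
        ps <- assimilate(ps, obs)
        ps <- maybe_resample(ps)
      }
      filters[[m]] <- ps
    }
    out[[cl]] <- list(particles = filters, obs_noise_sd = obs_sd,
                      seasadj = sa)
  }
  out
}
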