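# Synthetic case line lists and covariate tables with known ground truth ----

#' Configuration for the synthetic admission-series generator
#'
#' Defines the data-generating conditions the simulator emulates: roughly two
#' admissions per fortnight on average over 11 years (about 520 retained
#' cases), a strong spring (September-November) seasonal peak, a nonlinear
#' trend with a mid-series trough, negative-binomial overdispersion, lagged
#' environmental effects on the log-mean, about 5% misclassified
#' ("improbable") records and frequent re-recorded admissions.
#'
#' @param n_years number of simulated calendar years (>= 2).
#' @param start_year first simulated calendar year.
#' @param baseline mean admissions per fortnight at trend level 0 and seasonal
#'   factor 1.
#' @param seasonal_amplitudes length-24 positive multiplicative seasonal
#'   factors (geometric mean 1 for the default), peaking in fortnights 17-22.
#' @param trend_knots two-column matrix of (time fraction in \[0,1\], log-mean
#'   level) knots; the trend on the log-mean is their linear interpolation.
#' @param covariate_effects named list; each element is `list(lag = k, beta =
#'   b)` giving the linear coefficient `b` on the unit-scaled covariate lagged
#'   `k` fortnights. Names must be covariate-table columns or
#'   `"moist_vegetation"`.
#' @param phi negative-binomial overdispersion (> 0); variance is
#'   `mu + mu^2 / phi`.
#' @param false_positive_rate probability that a retained record is an
#'   improbable (misclassified) case.
#' @param duplicate_rate probability that a true admission is re-recorded
#'   within the dedup window.
#' @param duplicate_window_days maximum gap (days) between an admission and
#'   its injected duplicate.
#' @param ar_rho lag-1 autocorrelation of the AR(1) noise on climate series.
#' @param noise_scale multiplier on all covariate noise standard deviations
#'   (0 gives exactly periodic climate series).
#' @param clinic_ids labels of simulated clinics.
#' @param rng_seed integer seed making both generators deterministic.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_years = 11L,
                       start_year = 2007L,
                       baseline = 1.2,
                       seasonal_amplitudes = default_seasonal_amplitudes(),
                       trend_knots = cbind(time = c(0, 0.45, 1),
                                           level = c(0.35, -0.55, 0.45)),
                       covariate_effects = list(
                         SOI = list(lag = 2L, beta = 0.11),
                         max_temperature = list(lag = 2L, beta = -0.37),
                         moist_vegetation = list(lag = 6L, beta = 0.05)
                       ),
                       phi = 2,
                       false_positive_rate = 0.05,
                       duplicate_rate = 0.45,
                       duplicate_window_days = 14L,
                       ar_rho = 0.6,
                       noise_scale = 1,
                       clinic_ids = paste0("clinic_", 1:5),
                       rng_seed = 1L) {
  stopifnot(length(seasonal_amplitudes) == 24L, all(seasonal_amplitudes > 0),
            phi > 0,
            false_positive_rate >= 0, false_positive_rate <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            is.matrix(trend_knots), ncol(trend_knots) == 2L)
  structure(list(n_years = as.integer(n_years),
                 start_year = as.integer(start_year),
                 baseline = baseline,
                 seasonal_amplitudes = seasonal_amplitudes,
                 trend_knots = trend_knots,
                 covariate_effects = covariate_effects,
                 phi = phi,
                 false_positive_rate = false_positive_rate,
                 duplicate_rate = duplicate_rate,
                 duplicate_window_days = as.integer(duplicate_window_days),
                 ar_rho = ar_rho,
                 noise_scale = noise_scale,
                 clinic_ids = clinic_ids,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Default seasonal profile (September-November peak)
#'
#' Gaussian bump on the log scale centred between fortnights 19 and 20
#' (early-mid October), normalized to geometric mean 1.
#' @return length-24 positive numeric vector.
#' @export
default_seasonal_amplitudes <- function() {
  f <- 1:24
  # circular distance to the peak position
  d <- pmin(abs(f - 19.5), 24 - abs(f - 19.5))
  la <- 2.4 * exp(-d^2 / (2 * 3.0^2))
  exp(la - mean(la))
}

max_configured_lag <- function(config) {
  if (length(config$covariate_effects) == 0L) return(0L)
  max(vapply(config$covariate_effects, function(e) as.integer(e$lag), 1L))
}

ar1_series <- function(n, rho, sd_innov) {
  if (sd_innov == 0 || n == 0L) return(numeric(n))
  e <- rnorm(n, 0, sd_innov)
  x <- numeric(n)
  x[1L] <- e[1L] / sqrt(max(1 - rho^2, 1e-12))
  for (t in seq_len(n)[-1L]) x[t] <- rho * x[t - 1L] + e[t]
  x
}

#' Simulate a fortnightly environmental covariate table
#'
#' Climate series are a smooth within-year seasonal mean plus AR(1) noise;
#' the Southern Oscillation Index is a zero-mean AR(1); shrub and forest cover
#' change only between years. The table includes a lead-in of six fortnights
#' before the first simulated year so that lagged predictors are available
#' from the first admission fortnight.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `year`, `fortnight`, `date` (bin start) and
#'   the eight covariates (`max_temperature`, `min_temperature`, `rainfall`,
#'   `evapotranspiration`, `NDVI`, `SOI`, `shrub_cover`, `forest_cover`),
#'   one row per fortnight on a regular grid.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_years < 2L) stop("n_years must be >= 2 (lag selection needs history)")
  with_seed(config$rng_seed, {
    lead_in <- 6L
    years0 <- rep(config$start_year - 1L, lead_in)
    fns0 <- (24L - lead_in + 1L):24L
    years <- c(years0, rep(config$start_year + seq_len(config$n_years) - 1L,
                           each = 24L))
    fns <- c(fns0, rep(1:24, config$n_years))
    n <- length(years)
    f <- fns
    ns <- config$noise_scale
    rho <- config$ar_rho
    # southern-hemisphere seasonality: warm and wet around the new year
    season <- function(amp, phase) amp * cos(2 * pi * (f - phase) / 24)
    max_noise <- ar1_series(n, rho, 1.2 * ns)
    max_temperature <- 25 + 4.5 * season(1, 1) + max_noise
    # min temperature shares most of the max-temperature signal (collinear by
    # construction, as in the observed predictor set)
    min_temperature <- 15 + 4.8 * season(1, 1) +
      0.8 * max_noise + ar1_series(n, rho, 0.5 * ns)
    rainfall <- pmax(0, 60 + 35 * season(1, 2) + ar1_series(n, rho, 25 * ns))
    evapotranspiration <- pmax(0.1, 4 + 1.5 * season(1, 1) +
                                 ar1_series(n, rho, 0.35 * ns))
    NDVI <- pmin(0.95, pmax(0.05, 0.55 + 0.08 * season(1, 4) +
                              ar1_series(n, rho, 0.03 * ns)))
    SOI <- ar1_series(n, 0.9, 4 * ns)
    uy <- sort(unique(years))
    shrub_y <- pmin(1, pmax(0, 0.25 + cumsum(rnorm(length(uy), 0, 0.01 * ns))))
    forest_y <- pmin(1, pmax(0, 0.35 + cumsum(rnorm(length(uy), 0, 0.01 * ns))))
    shrub_cover <- shrub_y[match(years, uy)]
    forest_cover <- forest_y[match(years, uy)]
    data.frame(year = years, fortnight = fns,
               date = fortnight_start_date(years, fns),
               max_temperature = max_temperature,
               min_temperature = min_temperature,
               rainfall = rainfall,
               evapotranspiration = evapotranspiration,
               NDVI = NDVI, SOI = SOI,
               shrub_cover = shrub_cover, forest_cover = forest_cover)
  })
}

#' Simulate a case line list from covariates
#'
#' Fortnightly counts are negative-binomial draws whose log-mean is the sum of
#' a piecewise-linear trend, the log seasonal factor and linear effects of
#' lagged, unit-scaled covariates. Counts are expanded to dated records with
#' clinic and species labels; re-recorded admissions (duplicates) and
#' improbable (false-positive) records are injected at the configured rates.
#' Ground truth is returned as a separate table so pipeline code can never
#' consume it by accident.
#'
#' @param config a [sim_config()].
#' @param covariates table from [simulate_covariates()]; must cover all
#'   simulated fortnights plus the maximum configured lag.
#' @return a `tick_sim` list: `cases` (data.frame: `admission_date`,
#'   `clinic_id`, `species`, `record_class`), `truth` (data.frame: `year`,
#'   `fortnight`, `mu`, `count`), `counts` (a [fortnight_series()] of true
#'   deduplicated counts), `n_duplicates`, `n_false_positives`.
#' @export
simulate_cases <- function(config, covariates = simulate_covariates(config)) {
  stopifnot(inherits(config, "sim_config"))
  years <- config$start_year + seq_len(config$n_years) - 1L
  grid <- data.frame(year = rep(years, each = 24L),
                     fortnight = rep(1:24, config$n_years))
  key_cov <- paste(covariates$year, covariates$fortnight)
  key_grid <- paste(grid$year, grid$fortnight)
  idx <- match(key_grid, key_cov)
  if (anyNA(idx)) stop("covariates do not cover all simulated fortnights")
  maxlag <- max_configured_lag(config)
  if (any(idx - maxlag < 1L)) {
    stop("covariates must extend at least the maximum configured lag before the first simulated fortnight")
  }

  # linear predictor on the log-mean
  tt <- seq(0, 1, length.out = nrow(grid))
  trend <- approx(config$trend_knots[, 1L], config$trend_knots[, 2L],
                  xout = tt, rule = 2)$y
  log_mu <- log(config$baseline) + trend +
    log(config$seasonal_amplitudes[grid$fortnight])
  cov_ext <- covariates
  cov_ext$moist_vegetation <- moist_vegetation(
    covariates$rainfall, covariates$evapotranspiration,
    covariates$shrub_cover, covariates$forest_cover)
  for (nm in names(config$covariate_effects)) {
    if (!nm %in% names(cov_ext)) stop("covariate effect references unknown predictor: ", nm)
    eff <- config$covariate_effects[[nm]]
    x <- cov_ext[[nm]]
    z <- (x - mean(x)) / sd(x)
    log_mu <- log_mu + eff$beta * z[idx - as.integer(eff$lag)]
  }
  mu <- exp(log_mu)

  with_seed(config$rng_seed + 1L, {
    counts <- rnbinom(length(mu), mu = mu, size = config$phi)
    # expand counts to dated records
    n_rec <- sum(counts)
    rec_year <- rep(grid$year, counts)
    rec_fn <- rep(grid$fortnight, counts)
    if (n_rec > 0L) {
      ndays <- mapply(fortnight_n_days, rec_year, rec_fn)
      day_off <- floor(runif(n_rec) * ndays)
      dates <- fortnight_start_date(rec_year, rec_fn) + day_off
      clinics <- sample(config$clinic_ids, n_rec, replace = TRUE)
      species <- sample(c("dog", "cat"), n_rec, replace = TRUE,
                        prob = c(0.77, 0.23))
      rclass <- sample(c("confirmed", "probable"), n_rec, replace = TRUE,
                       prob = c(80, 15) / 95)
      cases <- data.frame(admission_date = dates, clinic_id = clinics,
                          species = species, record_class = rclass,
                          stringsAsFactors = FALSE)
    } else {
      cases <- data.frame(admission_date = as.Date(character()),
                          clinic_id = character(), species = character(),
                          record_class = character())
    }
    # re-recorded admissions within the dedup window
    is_dup <- runif(n_rec) < config$duplicate_rate
    n_dup <- sum(is_dup)
    if (n_dup > 0L) {
      dup <- cases[is_dup, , drop = FALSE]
      dup$admission_date <- pmin(
        dup$admission_date +
          sample.int(config$duplicate_window_days, n_dup, replace = TRUE),
        as.Date(sprintf("%04d-12-31", max(years))))
      cases <- rbind(cases, dup)
    }
    # improbable records, uniform over the simulated span (dilute seasonality)
    n_fp <- rpois(1L, n_rec * config$false_positive_rate /
                    max(1 - config$false_positive_rate, 1e-9))
    if (n_fp > 0L) {
      span <- as.integer(as.Date(sprintf("%04d-12-31", max(years))) -
                           as.Date(sprintf("%04d-01-01", min(years)))) + 1L
      fp <- data.frame(
        admission_date = as.Date(sprintf("%04d-01-01", min(years))) +
          floor(runif(n_fp) * span),
        clinic_id = sample(config$clinic_ids, n_fp, replace = TRUE),
        species = sample(c("dog", "cat"), n_fp, replace = TRUE,
                         prob = c(0.77, 0.23)),
        record_class = "improbable", stringsAsFactors = FALSE)
      cases <- rbind(cases, fp)
    }
    cases <- cases[order(cases$admission_date, cases$clinic_id), ]
    rownames(cases) <- NULL
    structure(list(cases = cases,
                   truth = data.frame(year = grid$year,
                                      fortnight = grid$fortnight,
                                      mu = mu, count = counts),
                   counts = fortnight_series(counts,
                                             start = c(years[1L], 1L)),
                   n_duplicates = n_dup,
                   n_false_positives = n_fp),
              class = "tick_sim")
  })
}

#' Write a simulation to CSV files
#'
#' Writes `cases.csv` (ISO-8601 dates), `covariates.csv` and
#' `ground_truth.csv` into `dir`.
#'
#' @param sim result of [simulate_cases()].
#' @param covariates the matching covariate table.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, covariates, dir) {
  stopifnot(inherits(sim, "tick_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("cases.csv", "covariates.csv", "ground_truth.csv"))
  write.csv(sim$cases, paths[1L], row.names = FALSE)
  write.csv(covariates, paths[2L], row.names = FALSE)
  write.csv(sim$truth, paths[3L], row.names = FALSE)
  invisible(paths)
}
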