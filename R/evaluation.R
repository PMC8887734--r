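# Train/validation/test splits and rolling-origin evaluation -------------

#' Split a fortnightly series into training, validation and test windows
#'
#' The training window takes `ceiling(train_fraction * T)` observations. The
#' held-out remainder is split so that the held-out bins before the final
#' calendar year form the weight-optimization validation window and the
#' final year forms the test window.
#'
#' @param series a [fortnight_series()].
#' @param train_fraction fraction of observations used for training
#'   (default 0.85).
#' @return list of [fortnight_series()]: `train`, `validation`, `test`.
#' @export
train_test_split <- function(series, train_fraction = 0.85) {
  Tn <- length(series)
  if (Tn < 48L) stop("series shorter than two seasonal cycles")
  n_train <- ceiling(train_fraction * Tn)
  if (n_train >= Tn) stop("empty held-out set; lower train_fraction")
  df <- as.data.frame(series)
  held <- (n_train + 1L):Tn
  last_year <- df$year[Tn]
  test_idx <- held[df$year[held] == last_year]
  val_idx <- setdiff(held, test_idx)
  if (length(val_idx) == 0L) {
    stop("no validation bins between training end and the final year")
  }
  sub <- function(idx) {
    fortnight_series(as.numeric(series)[idx],
                     start = c(df$year[idx[1L]], df$fortnight[idx[1L]]))
  }
  list(train = sub(1:n_train), validation = sub(val_idx), test = sub(test_idx))
}

#' Point errors of a forecast against observations
#'
#' Absolute error of the forecast median per horizon, with the median and
#' interquartile range across the evaluated horizons as summaries.
#'
#' @param forecast a [forecast_distribution()] or `combined_forecast`.
#' @param observed numeric observations for horizons `1..H'` (`H' <= H`);
#'   must overlap the forecast horizons.
#' @return list: `errors` per horizon, `median`, `iqr` (25% and 75%
#'   quantiles).
#' @export
point_errors <- function(forecast, observed) {
  med <- if (inherits(forecast, "forecast_distribution")) {
    summary(forecast)$median
  } else forecast$median
  Hn <- min(length(med), length(observed))
  if (Hn == 0L) stop("no overlap between forecast horizons and observations")
  e <- abs(med[seq_len(Hn)] - as.numeric(observed)[seq_len(Hn)])
  list(errors = e, median = median(e),
       iqr = unname(quantile(e, c(0.25, 0.75))))
}

#' Engineer the candidate predictor set from a raw covariate table
#'
#' Builds the engineered covariates (moist vegetation index, quarterly
#' anomalies), prunes collinear candidates at |r| > `threshold` with a
#' priority order, and selects per-predictor lags by cross-correlation with
#' the seasonally adjusted target, scaling to unit variance on the training
#' window. All statistics (anomaly climatology, correlations, scaling) use
#' only the supplied rows, so truncating the covariate table at a rolling
#' origin keeps the pipeline leakage-free.
#'
#' @param covariates covariate table (as from [simulate_covariates()]) whose
#'   final `length(seasadj)` rows align with the target.
#' @param seasadj seasonally adjusted training series.
#' @param threshold collinearity cutoff.
#' @param max_lag maximum candidate lag.
#' @param priority retention priority for [prune_collinear()].
#' @return a [select_lags()] predictor set.
#' @export
prepare_predictors <- function(covariates, seasadj, threshold = 0.70,
                               max_lag = 6L,
                               priority = c("moist_vegetation",
                                            "moist_vegetation_anomaly",
                                            "max_temperature",
                                            "max_temperature_anomaly",
                                            "NDVI_anomaly", "SOI",
                                            "min_temperature",
                                            "min_temperature_anomaly",
                                            "NDVI")) {
  cand <- engineer_covariates(covariates)
  keep <- prune_collinear(cand, threshold = threshold, priority = priority)
  select_lags(cand[keep], seasadj, max_lag = max_lag)
}

band_of_horizon <- function(h) {
  # near-term 1-6 fortnights (2-12 weeks), medium-term 6-12 (12-24 weeks);
  # fortnight 6 belongs to both as the bands share week 12
  list(near = h >= 1 & h <= 6, medium = h >= 6 & h <= 12)
}

#' Rolling-origin evaluation of benchmark, ensemble and filtered ensemble
#'
#' At each origin the benchmark and the requested ensemble members are
#' refit on all data up to the origin (the ARIMA member reuses the orders and
#' covariate subset selected at the first origin), weighted forecasts are
#' issued over the horizons, and 95% interval scores and absolute
#' median-point errors are recorded against the subsequently observed
#' counts. In `pf` mode the seasonally adjusted members are not refit after
#' the first origin: incoming observations are converted to the seasonally
#' adjusted scale (subtracting the STL seasonal component extended by the
#' seasonal exponential-smoothing forecast) and assimilated by particle
#' filter, while the count-scale members are refit as usual.
#'
#' @param counts full observed [fortnight_series()].
#' @param covariates covariate table whose final `length(counts)` rows align
#'   with `counts` (plus lead-in rows before).
#' @param origins integer training sizes (observations before the forecast
#'   origin), strictly increasing, advancing one fortnight at a time in the
#'   full protocol.
#' @param horizons forecast horizons in fortnights (default 1:12).
#' @param members subset of `c("arima_seasadj", "garch_seasadj", "gam_raw",
#'   "prophet_raw")`.
#' @param weights ensemble weights (named, aligned to `members`); equal
#'   weights if `NULL`.
#' @param pf also run the particle-filtered ensemble.
#' @param n_paths forecast sample paths per member.
#' @param n_particles particles per filtered member.
#' @param cfg [filter_config()] for the filters.
#' @param garch_args list of extra arguments to [fit_garch_seasadj()].
#' @param seed integer; every origin derives its own substream.
#' @param verbose log per-origin progress to stderr.
#' @return an `evaluation_report` data.frame with one row per (model,
#'   origin, horizon): `point_error`, `interval_score`, `band` flags.
#' @export
rolling_evaluate <- function(counts, covariates, origins, horizons = 1:12,
                             members = c("arima_seasadj", "gam_raw"),
                             weights = NULL, pf = FALSE, n_paths = 500L,
                             n_particles = 2000L, cfg = filter_config(),
                             garch_args = list(), seed = 1L,
                             verbose = FALSE) {
  Tn <- length(counts)
  stopifnot(all(diff(origins) > 0), max(origins) < Tn, min(origins) >= 72L)
  members <- match.arg(members, c("arima_seasadj", "garch_seasadj",
                                  "gam_raw", "prophet_raw"),
                       several.ok = TRUE)
  if (is.null(weights)) {
    weights <- setNames(rep(1 / length(members), length(members)), members)
  } else if (inherits(weights, "ensemble_weights")) {
    weights <- weights$weights
  }
  y_all <- as.numeric(counts)
  df_all <- as.data.frame(counts)
  n_lead <- nrow(covariates) - Tn
  if (n_lead < 0L) stop("covariate table shorter than the count series")

  arima_structure <- NULL
  pf_state <- NULL       # list(particles per member, seasonal ets, stl seasonal)
  rows <- list()
  add_row <- function(model, origin, h, pe, is_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      model = model, origin = origin, horizon = h,
      point_error = pe, interval_score = is_)
  }

  for (oi in seq_along(origins)) {
    o <- origins[oi]
    h_avail <- horizons[o + horizons <= Tn]
    if (length(h_avail) == 0L) next
    H <- max(h_avail)
    obs <- y_all[o + h_avail]
    seed_o <- (seed * 1000L + oi) %% .Machine$integer.max
    train <- fortnight_series(y_all[1:o],
                              start = c(df_all$year[1L], df_all$fortnight[1L]))
    cov_tr <- covariates[1:(n_lead + o), , drop = FALSE]
    dec <- stl_decompose(train)
    sa <- seasonally_adjust(dec)
    lp <- prepare_predictors(cov_tr, sa)
    ets_season <- fit_ets(dec$seasonal, target_scale = "seasonal_component")
    fc_season <- forecast(ets_season, H, n_paths = n_paths,
                          seed = seed_o + 1L)

    # benchmark
    bench <- fit_ets(train, target_scale = "log1p_count")
    fc_bench <- forecast(bench, H, n_paths = n_paths, seed = seed_o + 2L)
    sb <- summary(fc_bench)
    for (h in h_avail) {
      add_row("benchmark", o, h, abs(sb$median[h] - y_all[o + h]),
              interval_score(sb$lo95[h], sb$up95[h], y_all[o + h]))
    }

    # retrained members
    member_fcs <- list()
    failed <- character(0)
    for (m in members) {
      fc <- tryCatch({
        if (m == "arima_seasadj") {
          fit <- if (is.null(arima_structure)) {
            f0 <- fit_arima_seasadj(sa, lp)
            arima_structure <- list(order = f0$order,
                                    selected = f0$selected)
            f0
          } else {
            refit_arima(sa, lp, arima_structure)
          }
          f <- forecast(fit, H, n_paths = n_paths, seed = seed_o + 3L,
                        persist_covariates = TRUE)
          to_outcome_scale(f, fc_season)
        } else if (m == "garch_seasadj") {
          fit <- do.call(fit_garch_seasadj, c(list(sa, lp), garch_args))
          if (!fit$converged) stop("GARCH member did not converge")
          f <- forecast(fit, H, n_paths = n_paths, seed = seed_o + 4L,
                        persist_covariates = TRUE)
          to_outcome_scale(f, fc_season)
        } else if (m == "gam_raw") {
          fit <- fit_gam_raw(train, lp)
          forecast(fit, H, n_paths = n_paths, seed = seed_o + 5L,
                   persist_covariates = TRUE)
        } else {
          fit <- fit_prophet_raw(train, lp)
          forecast(fit, H, n_paths = n_paths, seed = seed_o + 6L,
                   persist_covariates = TRUE)
        }
      }, error = function(e) {
        warning("member ", m, " failed at origin ", o, ": ",
                conditionMessage(e))
        NULL
      })
      if (is.null(fc)) failed <- c(failed, m) else member_fcs[[m]] <- fc
    }
    if (length(member_fcs) > 0L) {
      w <- weights[names(member_fcs)]
      comb <- combine(member_fcs, w / sum(w))
      for (h in h_avail) {
        add_row("ensemble", o, h, abs(comb$median[h] - y_all[o + h]),
                interval_score(comb$lo95[h], comb$up95[h], y_all[o + h]))
      }
    }

    # particle-filtered ensemble: seasadj members assimilated, others refit
    if (pf) {
      sa_members <- intersect(members, c("arima_seasadj", "garch_seasadj"))
      if (oi == 1L) {
        # engineered predictor extension for assimilation-time regressors;
        # anomaly climatology frozen at the first origin's training window
        eng_ext <- engineer_covariates(
          covariates,
          climatology = seq_len(nrow(covariates)) <= n_lead + o)
        pf_state <- list(particles = list(), season_fit = ets_season,
                         seasonal_known = as.numeric(dec$seasonal),
                         origin0 = o, eng_ext = eng_ext)
        for (m in sa_members) {
          fit <- if (m == "arima_seasadj") {
            if (is.null(arima_structure)) {
              f0 <- fit_arima_seasadj(sa, lp)
              arima_structure <- list(order = f0$order,
                                      selected = f0$selected)
              f0
            } else refit_arima(sa, lp, arima_structure)
          } else {
            do.call(fit_garch_seasadj, c(list(sa, lp), garch_args))
          }
          pf_state$particles[[m]] <-
            init_particles(fit, n = n_particles, cfg = cfg,
                           covariates = eng_ext, seed = seed_o + 7L)
        }
      } else {
        # assimilate counts observed since the previous origin
        new_idx <- (origins[oi - 1L] + 1L):o
        for (t_new in new_idx) {
          j <- t_new - pf_state$origin0
          seas_t <- seasonal_component_at(pf_state, j)
          obs_sa <- y_all[t_new] - seas_t
          for (m in names(pf_state$particles)) {
            ps <- with_seed(seed_o + 8L + t_new, {
              p1 <- assimilate(pf_state$particles[[m]], obs_sa)
              maybe_resample(p1)
            })
            pf_state$particles[[m]] <- ps
          }
        }
      }
      pf_fcs <- list()
      seas_future <- vapply((o - pf_state$origin0) + seq_len(H),
                            function(j) seasonal_component_at(pf_state, j),
                            numeric(1))
      fc_season_pf <- forecast_distribution(
        matrix(rep(seas_future, each = n_paths), n_paths, H),
        member = "ets_seasonal", scale = "seasonal_component")
      for (m in names(pf_state$particles)) {
        # forecasting may only see covariates observed by the origin
        ps_fc <- pf_state$particles[[m]]
        ps_fc$covariates <- pf_state$eng_ext[1:(n_lead + o), , drop = FALSE]
        pf_fcs[[m]] <- with_seed(seed_o + 9L, {
          pf_forecast(ps_fc, H, fc_season_pf, persist_covariates = TRUE)
        })
      }
      for (m in setdiff(names(member_fcs), names(pf_fcs))) {
        pf_fcs[[m]] <- member_fcs[[m]]
      }
      if (length(pf_fcs) > 0L) {
        w <- weights[names(pf_fcs)]
        comb <- combine(pf_fcs, w / sum(w))
        for (h in h_avail) {
          add_row("pf_ensemble", o, h, abs(comb$median[h] - y_all[o + h]),
                  interval_score(comb$lo95[h], comb$up95[h], y_all[o + h]))
        }
      }
    }
    if (verbose) message(sprintf("origin %d done (%d/%d)", o, oi,
                                 length(origins)))
  }
  rep <- do.call(rbind, rows)
  bands <- band_of_horizon(rep$horizon)
  rep$near_term <- bands$near
  rep$medium_term <- bands$medium
  class(rep) <- c("evaluation_report", "data.frame")
  rep
}

# seasonal component j fortnights after the first rolling origin: known STL
# seasonal values inside the first training window, exponential-smoothing
# mean forecast beyond it
seasonal_component_at <- function(pf_state, j) {
  if (j <= 0L) {
    s <- pf_state$seasonal_known
    return(s[length(s) + j])
  }
  ets_mean_forecast(pf_state$season_fit$fit, j)[j]
}

# refit an ARIMA member with a fixed structure (orders + covariate subset)
refit_arima <- function(sa, lp, struct) {
  y <- as.numeric(sa)
  xreg <- if (length(struct$selected)) {
    lp$x[, struct$selected, drop = FALSE]
  } else NULL
  fit <- try_arima(y, struct$order, xreg)
  if (is.null(fit)) {
    fit <- try_arima(y, c(1L, 0L, 0L), xreg)
    if (is.null(fit)) stop("ARIMA refit failed")
    struct$order <- c(1L, 0L, 0L)
  }
  cf <- coef(fit)
  se <- sqrt(pmax(diag(fit$var.coef), 0))
  structure(list(member = "arima_seasadj",
                 target_scale = "seasonally_adjusted",
                 fit = fit, order = struct$order,
                 selected = struct$selected, bic = BIC(fit),
                 coefficients = data.frame(term = names(cf),
                                           estimate = unname(cf),
                                           se = unname(se)),
                 sigma = sqrt(fit$sigma2),
                 y = y, candidates = lp),
            class = c("member_arima", "tickcast_member"))
}

#' Summarize an evaluation report
#'
#' Per-model median and interquartile range of point errors, mean 95%
#' interval score by horizon band, and (against the benchmark) the fraction
#' of origins each model wins on mean interval score.
#'
#' @param report an [rolling_evaluate()] result.
#' @return data.frame, one row per model.
#' @export
compare_report <- function(report) {
  stopifnot(nrow(report) > 0L)
  models <- unique(report$model)
  per_origin <- function(m) {
    sub <- report[report$model == m, ]
    tapply(sub$interval_score, sub$origin, mean)
  }
  bench_po <- if ("benchmark" %in% models) per_origin("benchmark") else NULL
  out <- do.call(rbind, lapply(models, function(m) {
    sub <- report[report$model == m, ]
    po <- per_origin(m)
    win <- if (!is.null(bench_po) && m != "benchmark") {
      common <- intersect(names(po), names(bench_po))
      mean(po[common] < bench_po[common])
    } else NA_real_
    data.frame(model = m,
               point_error_median = median(sub$point_error),
               point_error_q25 = unname(quantile(sub$point_error, 0.25)),
               point_error_q75 = unname(quantile(sub$point_error, 0.75)),
               interval_score_near = mean(sub$interval_score[sub$near_term]),
               interval_score_medium = mean(sub$interval_score[sub$medium_term]),
               win_fraction_vs_benchmark = win)
  }))
  rownames(out) <- NULL
  out
}
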