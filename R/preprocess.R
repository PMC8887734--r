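# Record dedup, fortnight binning, STL adjustment, predictor engineering ----

#' Remove re-recorded admissions
#'
#' Within each (clinic, species) stream, any record dated within `window_days`
#' after a retained record is dropped (greedy forward pass), mirroring
#' clinical re-presentations of the same animal. Improbable records are kept:
#' record retrieval is assumed ~95% specific and no class is filtered here.
#'
#' @param records data.frame with `admission_date`, `clinic_id`, `species`
#'   (and any further columns, preserved).
#' @param window_days nonnegative integer; records this many days or fewer
#'   after a retained record in the same stream are duplicates.
#' @return the deduplicated data.frame, original row order preserved.
#' @export
dedupe_cases <- function(records, window_days = 14L) {
  if (window_days < 0) stop("window_days must be nonnegative")
  if (nrow(records) == 0L) return(records)
  d <- as.Date(records$admission_date)
  key <- paste(records$clinic_id, records$species, sep = "\r")
  keep <- logical(nrow(records))
  ord <- order(key, d)
  last_key <- ""
  last_date <- as.Date("0001-01-01")
  for (i in ord) {
    if (key[i] != last_key || as.integer(d[i] - last_date) > window_days) {
      keep[i] <- TRUE
      last_key <- key[i]
      last_date <- d[i]
    }
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin dated records into fortnightly counts
#'
#' Days 1-15 of a month fall in the first bin, day 16 onward in the second;
#' empty bins are zero-filled so the grid is complete.
#'
#' @param records data.frame with an `admission_date` column.
#' @param start_year,end_year inclusive calendar-year range of the grid; all
#'   record dates must fall inside it.
#' @return a [fortnight_series()] of counts, length `24 * n_years`.
#' @export
bin_fortnights <- function(records, start_year, end_year) {
  stopifnot(end_year >= start_year)
  n_years <- end_year - start_year + 1L
  counts <- numeric(24L * n_years)
  if (nrow(records) > 0L) {
    d <- as.Date(records$admission_date)
    yr <- as.integer(format(d, "%Y"))
    if (any(yr < start_year | yr > end_year)) {
      stop("record dates outside [start_year, end_year]")
    }
    fn <- fortnight_of_date(d)
    pos <- (yr - start_year) * 24L + fn
    tab <- table(pos)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  fortnight_series(counts, start = c(start_year, 1L))
}

#' Seasonal-trend decomposition by Loess
#'
#' Additive STL split of a fortnightly series into seasonal, trend and
#' remainder components. The seasonal component is a Loess smooth over each of
#' the 24 seasonal sub-series; the trend is the Loess smooth of the
#' deseasonalized series; the remainder is the residual, so the three
#' components sum exactly to the input.
#'
#' @param series a [fortnight_series()] (or `ts`) of length at least two full
#'   cycles.
#' @param s_window seasonal Loess span: `"periodic"` or an odd integer. The
#'   default is a large window giving a near-periodic, slowly evolving
#'   seasonal shape.
#' @param t_window optional trend Loess span (odd integer); STL's default
#'   otherwise.
#' @param robust use robust Loess iterations.
#' @return an `stl_decomposition` list with `seasonal`, `trend`, `remainder`
#'   and the original `series`, all aligned.
#' @export
stl_decompose <- function(series, s_window = 25, t_window = NULL,
                          robust = FALSE) {
  p <- frequency(series)
  if (length(series) < 2L * p) stop("series shorter than two seasonal cycles")
  fit <- if (is.null(t_window)) {
    stl(series, s.window = s_window, robust = robust)
  } else {
    stl(series, s.window = s_window, t.window = t_window, robust = robust)
  }
  comp <- fit$time.series
  out <- list(seasonal = copy_fs(comp[, "seasonal"], series),
              trend = copy_fs(comp[, "trend"], series),
              remainder = copy_fs(comp[, "remainder"], series),
              series = series)
  class(out) <- "stl_decomposition"
  out
}

# carry a component over to the fortnight_series class/time base of `template`
copy_fs <- function(values, template) {
  x <- ts(as.numeric(values), start = stats::start(template),
          frequency = frequency(template))
  class(x) <- class(template)
  x
}

#' Seasonally adjusted series (trend + remainder)
#'
#' @param decomp an [stl_decompose()] result.
#' @return a [fortnight_series()]; adding back the seasonal component
#'   reproduces the original series exactly.
#' @export
seasonally_adjust <- function(decomp) {
  stopifnot(inherits(decomp, "stl_decomposition"))
  copy_fs(as.numeric(decomp$trend) + as.numeric(decomp$remainder),
          decomp$series)
}

#' Moist-vegetation index
#'
#' Combines rainfall, evapotranspiration and woody-cover proportions into a
#' single moisture-availability predictor. The default convention is the
#' product form `rainfall * (-evapotranspiration) * (shrub + forest)`; the
#' `"deficit"` convention uses the water balance
#' `(rainfall - evapotranspiration) * (shrub + forest)`, which increases with
#' rainfall and decreases with evapotranspiration.
#'
#' @param rainfall,evapotranspiration,shrub_cover,forest_cover aligned numeric
#'   series of equal length.
#' @param convention `"product"` (default) or `"deficit"`.
#' @return numeric series.
#' @export
moist_vegetation <- function(rainfall, evapotranspiration, shrub_cover,
                             forest_cover,
                             convention = c("product", "deficit")) {
  convention <- match.arg(convention)
  n <- length(rainfall)
  if (length(evapotranspiration) != n || length(shrub_cover) != n ||
      length(forest_cover) != n) {
    stop("inputs must be aligned series of equal length")
  }
  cover <- shrub_cover + forest_cover
  switch(convention,
         product = rainfall * (-1 * evapotranspiration) * cover,
         deficit = (rainfall - evapotranspiration) * cover)
}

#' Quarterly anomalies of a fortnightly covariate
#'
#' For each fortnight, the anomaly is the mean of the covariate over the
#' calendar quarter it falls in (Jan-Mar, Apr-Jun, Jul-Sep, Oct-Dec, that
#' year) minus the long-term mean of that quarter, so it describes how the
#' current quarter's conditions compare with the typical conditions for that
#' part of the year. Long-term quarter means are computed over the
#' climatology window only. A series that repeats identically every year has
#' zero anomalies everywhere.
#'
#' @param x numeric covariate series.
#' @param fortnight integer vector (1-24) aligned to `x`.
#' @param year integer year labels aligned to `x`.
#' @param climatology logical vector aligned to `x` selecting the rows used to
#'   compute long-term quarter means (defaults to all rows); must span at
#'   least two full years' worth of observations.
#' @return numeric anomaly series aligned to `x` (constant within each
#'   year-quarter).
#' @export
quarterly_anomaly <- function(x, fortnight, year,
                              climatology = rep(TRUE, length(x))) {
  stopifnot(length(fortnight) == length(x), length(year) == length(x),
            length(climatology) == length(x))
  if (sum(climatology) < 48L) {
    stop("climatology window must span at least two full years")
  }
  q <- quarter_of_fortnight(fortnight)
  qm <- tapply(x[climatology], q[climatology], mean)
  if (length(qm) < 4L || anyNA(qm)) {
    stop("climatology window must cover all four quarters")
  }
  yq <- paste(year, q)
  yqm <- tapply(x, yq, mean)
  as.numeric(yqm[yq]) - as.numeric(qm[as.character(q)])
}

#' Engineered candidate covariates
#'
#' Builds the candidate predictor columns from a raw covariate table: the
#' moist vegetation index, quarterly anomalies of moist vegetation and the
#' temperature/NDVI series, the raw temperature and NDVI series, and the
#' Southern Oscillation Index. Anomalies are computed against the climatology
#' rows only, so the same function serves both model training and real-time
#' extension of the predictor table (with the climatology frozen at the
#' training window).
#'
#' @param covariates raw covariate table (columns as in
#'   [simulate_covariates()]).
#' @param climatology logical vector over rows used for anomaly climatology.
#' @return data.frame of nine candidate predictors aligned to `covariates`.
#' @export
engineer_covariates <- function(covariates,
                                climatology = rep(TRUE, nrow(covariates))) {
  mv <- moist_vegetation(covariates$rainfall, covariates$evapotranspiration,
                         covariates$shrub_cover, covariates$forest_cover)
  fn <- covariates$fortnight
  yr <- covariates$year
  qa <- function(x) quarterly_anomaly(x, fn, yr, climatology)
  data.frame(
    moist_vegetation = mv,
    moist_vegetation_anomaly = qa(mv),
    max_temperature = covariates$max_temperature,
    max_temperature_anomaly = qa(covariates$max_temperature),
    min_temperature = covariates$min_temperature,
    min_temperature_anomaly = qa(covariates$min_temperature),
    NDVI = covariates$NDVI,
    NDVI_anomaly = qa(covariates$NDVI),
    SOI = covariates$SOI)
}

#' Drop collinear covariates
#'
#' Greedy pruning: while any retained pair has absolute Pearson correlation
#' above `threshold`, the lower-priority member of the most correlated pair is
#' dropped. Priority follows `priority` (earlier = kept), defaulting to column
#' order, which lets the caller encode choices such as preferring maximum over
#' minimum temperature and an anomaly over its raw series.
#'
#' @param covariates data.frame or matrix of candidate covariates (>= 2).
#' @param threshold absolute-correlation cutoff (default 0.70).
#' @param priority character vector of column names in decreasing priority.
#' @return character vector of retained column names.
#' @export
prune_collinear <- function(covariates, threshold = 0.70,
                            priority = colnames(covariates)) {
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) < 2L) stop("need at least two covariates")
  keep <- colnames(covariates)
  rank <- match(keep, priority)
  rank[is.na(rank)] <- length(priority) + seq_len(sum(is.na(rank)))
  names(rank) <- keep
  repeat {
    if (length(keep) < 2L) break
    cm <- abs(cor(covariates[keep]))
    diag(cm) <- 0
    if (max(cm) <= threshold) break
    worst <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    pair <- keep[worst]
    drop <- pair[which.max(rank[pair])]
    keep <- setdiff(keep, drop)
  }
  keep
}

#' Select predictor lags by cross-correlation and scale to unit variance
#'
#' For each covariate, the lag in `1..max_lag` whose lagged values correlate
#' most strongly (in absolute value) with the target series is selected, with
#' ties broken toward the smaller lag. Selected lagged series are centred and
#' scaled to unit standard deviation on the training window; the scaling
#' parameters are retained so future regressor rows can be built identically.
#'
#' @param covariates data.frame of covariate columns on the fortnight grid,
#'   with `lead_in = nrow(covariates) - length(target)` extra rows *before*
#'   the target window (`lead_in >= max_lag`); the final `length(target)` rows
#'   align with the target.
#' @param target the (typically seasonally adjusted) training series.
#' @param max_lag maximum lag in fortnights (default 6).
#' @param weak_threshold lags whose best absolute correlation falls below this
#'   are flagged `weak` in the output (still returned).
#' @return a `lagged_predictors` object: matrix `x` (rows aligned to target)
#'   of scaled lagged predictors plus per-predictor `lag`, `cor`, `center`,
#'   `scale`, `weak`, and the raw covariate table for building future rows.
#' @export
select_lags <- function(covariates, target, max_lag = 6L,
                        weak_threshold = 0.2) {
  covariates <- as.data.frame(covariates)
  n <- length(target)
  lead_in <- nrow(covariates) - n
  if (lead_in < max_lag) {
    stop("covariates must extend at least max_lag fortnights before the target start")
  }
  y <- as.numeric(target)
  nm <- colnames(covariates)
  lags <- integer(length(nm)); cors <- numeric(length(nm))
  centers <- numeric(length(nm)); scales <- numeric(length(nm))
  xmat <- matrix(NA_real_, n, length(nm), dimnames = list(NULL, nm))
  for (j in seq_along(nm)) {
    xj <- covariates[[j]]
    if (sd(xj) == 0) stop("zero-variance covariate: ", nm[j])
    cc <- vapply(seq_len(max_lag), function(k) {
      cor(xj[lead_in + seq_len(n) - k], y)
    }, numeric(1))
    best <- which.max(abs(cc))  # ties go to the smaller lag
    lags[j] <- best
    cors[j] <- cc[best]
    xl <- xj[lead_in + seq_len(n) - best]
    centers[j] <- mean(xl)
    scales[j] <- sd(xl)
    xmat[, j] <- (xl - centers[j]) / scales[j]
  }
  structure(list(x = xmat, names = nm, lag = setNames(lags, nm),
                 cor = setNames(cors, nm),
                 center = setNames(centers, nm),
                 scale = setNames(scales, nm),
                 weak = setNames(abs(cors) < weak_threshold, nm),
                 covariates = covariates, lead_in = lead_in, n = n),
            class = "lagged_predictors")
}

#' Future regressor rows for forecasting
#'
#' Builds the scaled lagged predictor rows for horizons `1..horizon` beyond
#' the training window. Because every predictor enters at lag >= 1, the
#' covariate values needed are already observed up to horizon
#' `min(selected lags)`; beyond that, rows are only available when
#' `persist = TRUE` carries the last observed covariate value forward.
#'
#' @param lp a [select_lags()] result.
#' @param horizon number of fortnights ahead.
#' @param persist carry the last observed covariate forward when a horizon
#'   exceeds a predictor's lag.
#' @param covariates covariate table to draw future rows from; defaults to
#'   the training table stored in `lp`. Supplying an extension of that table
#'   (same grid, extra rows appended, as when observations keep arriving)
#'   makes later rows available without persistence.
#' @param offset shift (in fortnights) of the forecast origin beyond the end
#'   of `lp`'s training window; horizons count from the shifted origin.
#' @param vars predictor names to build rows for (default all).
#' @return matrix with `horizon` rows, one column per requested predictor.
#' @export
future_xreg <- function(lp, horizon, persist = FALSE,
                        covariates = lp$covariates, offset = 0L,
                        vars = lp$names) {
  stopifnot(inherits(lp, "lagged_predictors"), horizon >= 1,
            all(vars %in% lp$names))
  out <- matrix(NA_real_, horizon, length(vars),
                dimnames = list(NULL, vars))
  n_obs <- nrow(covariates)
  for (nm in vars) {
    k <- lp$lag[[nm]]
    rows <- lp$lead_in + lp$n + offset + seq_len(horizon) - k
    if (any(rows > n_obs)) {
      if (!persist) {
        stop(sprintf(
          "horizon %d exceeds lag %d for predictor '%s'; covariates unavailable (set persist = TRUE to carry last value forward)",
          horizon, k, nm))
      }
      rows <- pmin(rows, n_obs)
    }
    out[, nm] <- (covariates[[nm]][rows] - lp$center[[nm]]) / lp$scale[[nm]]
  }
  out
}
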