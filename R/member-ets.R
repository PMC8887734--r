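# Exponential smoothing member: benchmark and seasonal forecaster --------

#' Fit an exponential smoothing member
#'
#' State-space exponential smoothing with error/trend/seasonal components
#' chosen automatically by information criterion (see [ets_fit()]). Two uses:
#' the benchmark forecaster, trained on `log(count + 1)` transformed
#' admissions and back-transformed to the count scale, and the
#' seasonal-component forecaster that restores seasonality to the seasonally
#' adjusted members' forecasts.
#'
#' @param series the series to smooth: raw counts for the benchmark
#'   (`target_scale = "log1p_count"`), an STL seasonal component for the
#'   seasonal forecaster, or an already-adjusted series.
#' @param target_scale one of `"log1p_count"`, `"seasonal_component"`,
#'   `"seasonally_adjusted"`, `"raw_count"`.
#' @param m seasonal period.
#' @param model `"auto"` or an explicit structure like `"AAA"`.
#' @return a `member_ets` fit.
#' @export
fit_ets <- function(series, target_scale = c("log1p_count",
                                             "seasonal_component",
                                             "seasonally_adjusted",
                                             "raw_count"),
                    m = 24L, model = "auto") {
  target_scale <- match.arg(target_scale)
  y <- as.numeric(series)
  if (length(y) < 3L * m) {
    stop("series shorter than three full seasonal cycles")
  }
  z <- if (target_scale == "log1p_count") log1p(y) else y
  fit <- ets_fit(z, m = m, model = model)
  nm <- if (target_scale == "log1p_count") "ets_benchmark" else
    if (target_scale == "seasonal_component") "ets_seasonal" else "ets"
  structure(list(member = nm, target_scale = target_scale,
                 fit = fit, sigma = fit$sigma, y = y),
            class = c("member_ets", "tickcast_member"))
}

#' @describeIn fit_ets simulate forecast sample paths; benchmark paths are
#'   back-transformed with `exp(.) - 1` and truncated at zero.
#' @param object fitted member.
#' @param horizon fortnights ahead.
#' @param n_paths sample trajectories.
#' @param seed optional integer seed.
#' @param ... unused.
#' @export
forecast.member_ets <- function(object, horizon, n_paths = 1000,
                                seed = NULL, ...) {
  stopifnot(horizon >= 1)
  run <- function() {
    paths <- ets_simulate(object$fit, horizon, n_paths)
    scale <- switch(object$target_scale,
                    log1p_count = , raw_count = "count",
                    seasonal_component = "seasonal_component",
                    seasonally_adjusted = "seasonally_adjusted")
    if (object$target_scale == "log1p_count") {
      paths <- pmax(expm1(paths), 0)
    } else if (object$target_scale == "raw_count") {
      paths <- pmax(paths, 0)
    }
    forecast_distribution(paths, origin = length(object$y),
                          member = object$member, scale = scale)
  }
  if (!is.null(seed)) with_seed(seed, run()) else run()
}
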