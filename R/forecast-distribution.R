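# Sample-path forecast distributions -------------------------------------

#' Construct a forecast distribution from sample paths
#'
#' All members, the ensemble and the particle filter share this
#' representation: `S` sample trajectories over horizons `1..H`, optionally
#' weighted (particle filters attach importance weights).
#'
#' @param paths numeric matrix, `S` rows (paths) by `H` columns (horizons).
#' @param origin time index (in fortnights, e.g. `time(series)` value) of the
#'   last training observation.
#' @param member label of the generating model.
#' @param scale one of `"seasonally_adjusted"`, `"count"`, `"log1p_count"`.
#' @param weights optional length-`S` nonnegative path weights (normalized
#'   internally); default uniform.
#' @return a `forecast_distribution` object.
#' @export
forecast_distribution <- function(paths, origin = NA_real_,
                                  member = "unknown",
                                  scale = c("seasonally_adjusted", "count",
                                            "log1p_count",
                                            "seasonal_component"),
                                  weights = NULL) {
  scale <- match.arg(scale)
  paths <- as.matrix(paths)
  if (!is.null(weights)) {
    stopifnot(length(weights) == nrow(paths), all(weights >= 0),
              sum(weights) > 0)
    weights <- weights / sum(weights)
  }
  structure(list(paths = paths, origin = origin,
                 horizons = seq_len(ncol(paths)), member = member,
                 scale = scale, weights = weights),
            class = "forecast_distribution")
}

#' Weighted quantiles
#'
#' Quantile of a weighted sample, by inversion of the weighted empirical CDF
#' (left-continuous step interpolation). With uniform weights this matches
#' type-1 sample quantiles.
#'
#' @param x numeric sample.
#' @param w nonnegative weights (recycled uniform if `NULL`).
#' @param probs probabilities.
#' @return numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w = NULL, probs = 0.5) {
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(w) == length(x), all(w >= 0), sum(w) > 0)
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1L]], numeric(1))
}

#' Interval summary of a forecast distribution
#'
#' @param object a [forecast_distribution()].
#' @param levels central interval coverages to report.
#' @param ... unused.
#' @return data.frame with one row per horizon: `median` and lower/upper
#'   bounds per level (columns `lo95`, `lo80`, `up80`, `up95` for the
#'   defaults), satisfying `lo95 <= lo80 <= median <= up80 <= up95`.
#' @export
summary.forecast_distribution <- function(object, levels = c(0.8, 0.95),
                                          ...) {
  probs <- sort(unique(c(0.5, (1 - levels) / 2, 1 - (1 - levels) / 2)))
  qs <- apply(object$paths, 2L, weighted_quantile, w = object$weights,
              probs = probs)
  qs <- matrix(qs, nrow = length(probs))
  out <- data.frame(horizon = object$horizons,
                    median = qs[probs == 0.5, ])
  for (lv in sort(levels)) {
    out[[sprintf("lo%d", round(100 * lv))]] <- qs[probs == (1 - lv) / 2, ]
    out[[sprintf("up%d", round(100 * lv))]] <- qs[probs == 1 - (1 - lv) / 2, ]
  }
  out
}

#' @export
print.forecast_distribution <- function(x, ...) {
  cat(sprintf("Forecast distribution (%s, %s scale): %d paths x %d horizons\n",
              x$member, x$scale, nrow(x$paths), ncol(x$paths)))
  print(summary(x))
  invisible(x)
}

#' @export
plot.forecast_distribution <- function(x, ...) {
  s <- summary(x)
  graphics::plot(s$horizon, s$median, type = "l", lwd = 2,
                 ylim = range(s[, -1]), xlab = "horizon (fortnights)",
                 ylab = x$scale, ...)
  graphics::polygon(c(s$horizon, rev(s$horizon)), c(s$lo95, rev(s$up95)),
                    col = grDevices::adjustcolor("steelblue", 0.25),
                    border = NA)
  graphics::polygon(c(s$horizon, rev(s$horizon)), c(s$lo80, rev(s$up80)),
                    col = grDevices::adjustcolor("steelblue", 0.45),
                    border = NA)
  graphics::lines(s$horizon, s$median, lwd = 2)
  invisible(x)
}

#' Move a seasonally adjusted forecast to the count (outcome) scale
#'
#' Adds seasonal forecast paths to seasonally adjusted forecast paths
#' pathwise (path i + path i; the seasonal paths are recycled or subsampled to
#' match), then truncates at zero: negative admissions are meaningless.
#'
#' @param seasadj_forecast forecast on the seasonally adjusted scale.
#' @param seasonal_forecast forecast of the seasonal component over the same
#'   horizons (same origin).
#' @return a [forecast_distribution()] on the count scale.
#' @export
to_outcome_scale <- function(seasadj_forecast, seasonal_forecast) {
  stopifnot(inherits(seasadj_forecast, "forecast_distribution"),
            inherits(seasonal_forecast, "forecast_distribution"))
  if (ncol(seasadj_forecast$paths) != ncol(seasonal_forecast$paths)) {
    stop("horizon mismatch between seasonally adjusted and seasonal forecasts")
  }
  S <- nrow(seasadj_forecast$paths)
  sp <- seasonal_forecast$paths
  if (nrow(sp) != S) {
    sp <- sp[rep_len(seq_len(nrow(sp)), S), , drop = FALSE]
  }
  forecast_distribution(pmax(seasadj_forecast$paths + sp, 0),
                        origin = seasadj_forecast$origin,
                        member = seasadj_forecast$member,
                        scale = "count",
                        weights = seasadj_forecast$weights)
}
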