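# Interval scoring and convex ensemble weighting -------------------------

#' Interval score of a prediction interval
#'
#' Penalized interval width: `(U - L) + c*(L - Y)*[Y < L] + c*(Y - U)*[Y > U]`.
#' Under the standard convention (`"two_over_alpha"`) the penalty coefficient
#' is `c = 2 / alpha`, which rewards narrow intervals that still contain the
#' observation; the `"two_times_alpha"` convention uses `c = 2 * alpha`
#' instead. Vectorized over observations.
#'
#' @param lower,upper interval bounds (`lower <= upper` elementwise).
#' @param y observations.
#' @param alpha significance level of the interval (default 0.05 for a 95%
#'   interval).
#' @param penalty penalty convention.
#' @return numeric vector of scores.
#' @export
interval_score <- function(lower, upper, y, alpha = 0.05,
                           penalty = c("two_over_alpha", "two_times_alpha")) {
  penalty <- match.arg(penalty)
  if (any(lower > upper)) stop("interval has lower > upper")
  stopifnot(alpha > 0, alpha < 1)
  cc <- if (penalty == "two_over_alpha") 2 / alpha else 2 * alpha
  (upper - lower) +
    cc * (lower - y) * (y < lower) +
    cc * (y - upper) * (y > upper)
}

#' Weighted average of member prediction intervals
#'
#' Quantile averaging: the combined lower (upper) bound is the weighted mean
#' of the member lower (upper) bounds; medians combine identically.
#'
#' @param lowers,uppers numeric vectors, one entry per member.
#' @param weights convex weights (same length; normalized internally).
#' @return list with `lower` and `upper`.
#' @export
weighted_interval <- function(lowers, uppers, weights) {
  if (length(lowers) != length(weights) || length(uppers) != length(weights)) {
    stop("weights and member intervals have mismatched lengths")
  }
  w <- weights / sum(weights)
  list(lower = sum(w * lowers), upper = sum(w * uppers))
}

# Flatten member forecasts + observations into score-ready arrays:
# L, U, M: members x observation matrices of 95% bounds and medians.
ensemble_arrays <- function(member_forecasts, observations, level = 0.95) {
  stopifnot(length(member_forecasts) >= 2L)
  get_summ <- function(fc) {
    if (inherits(fc, "forecast_distribution")) {
      summary(fc, levels = level)
    } else if (is.list(fc) && all(vapply(fc, inherits, TRUE,
                                         "forecast_distribution"))) {
      do.call(rbind, lapply(fc, summary, levels = level))
    } else stop("member forecasts must be forecast_distribution objects")
  }
  ss <- lapply(member_forecasts, get_summ)
  n_obs <- nrow(ss[[1L]])
  if (length(observations) != n_obs) {
    stop("observations do not align with member forecast horizons")
  }
  lv <- round(100 * level)
  list(L = t(vapply(ss, function(s) s[[paste0("lo", lv)]], numeric(n_obs))),
       U = t(vapply(ss, function(s) s[[paste0("up", lv)]], numeric(n_obs))),
       M = t(vapply(ss, function(s) s$median, numeric(n_obs))),
       y = as.numeric(observations))
}

mean_weighted_score <- function(w, L, U, y, alpha, penalty) {
  lw <- as.numeric(crossprod(L, w))
  uw <- as.numeric(crossprod(U, w))
  mean(interval_score(lw, uw, y, alpha, penalty))
}

#' Optimize convex ensemble weights by mean interval score
#'
#' Minimizes the mean 95% interval score of the weighted member intervals
#' over a validation window, subject to weights being nonnegative and summing
#' to one. The simplex constraint is handled by a softmax reparameterization
#' and multi-start gradient-free optimization; every simplex corner (each
#' single member) and the equal-weight point are always evaluated as
#' candidates, so the optimized score never exceeds the best single member's.
#'
#' @param member_forecasts named list (one element per member) of
#'   [forecast_distribution()] objects — or lists of them spanning several
#'   origins — covering the validation window. Alternatively a list with
#'   numeric matrices `L` and `U` (members x observations) may be supplied
#'   directly.
#' @param observations observed values aligned to the stacked forecast
#'   horizons.
#' @param alpha interval significance level.
#' @param penalty penalty convention, as in [interval_score()].
#' @param n_restarts random optimizer restarts (default 25).
#' @param seed seed for the restart draws.
#' @return an `ensemble_weights` object: `weights` (named, on the simplex),
#'   `score` achieved, `member_scores` of the corners, and the config used.
#' @export
optimize_weights <- function(member_forecasts, observations, alpha = 0.05,
                             penalty = c("two_over_alpha",
                                         "two_times_alpha"),
                             n_restarts = 25L, seed = 1L) {
  penalty <- match.arg(penalty)
  if (!is.null(member_forecasts$L) && !is.null(member_forecasts$U)) {
    L <- as.matrix(member_forecasts$L)
    U <- as.matrix(member_forecasts$U)
    y <- as.numeric(observations)
    if (length(y) != ncol(L)) stop("observations do not align with intervals")
  } else {
    arr <- ensemble_arrays(member_forecasts, observations)
    L <- arr$L; U <- arr$U; y <- arr$y
  }
  M <- nrow(L)
  if (M < 2L) stop("need at least two members")
  if (ncol(L) < 1L) stop("validation window is empty")
  nms <- rownames(L)
  if (is.null(nms)) nms <- names(member_forecasts)[seq_len(M)]
  if (is.null(nms)) nms <- paste0("member_", seq_len(M))
  fobj <- function(v) {
    w <- exp(c(0, v) - max(c(0, v)))
    mean_weighted_score(w / sum(w), L, U, y, alpha, penalty)
  }
  corner_scores <- vapply(seq_len(M), function(i) {
    mean_weighted_score(as.numeric(seq_len(M) == i), L, U, y, alpha, penalty)
  }, numeric(1))
  best_w <- as.numeric(seq_len(M) == which.min(corner_scores))
  best_score <- min(corner_scores)
  eq <- rep(1 / M, M)
  eq_score <- mean_weighted_score(eq, L, U, y, alpha, penalty)
  if (eq_score < best_score) { best_w <- eq; best_score <- eq_score }
  starts <- with_seed(seed, {
    c(list(rep(0, M - 1L)),
      lapply(seq_len(n_restarts), function(i) rnorm(M - 1L, 0, 2)))
  })
  converged <- FALSE
  for (v0 in starts) {
    op <- tryCatch({
      if (M == 2L) {
        o <- stats::optimize(fobj, c(v0 - 15, v0 + 15), tol = 1e-10)
        list(par = o$minimum, value = o$objective)
      } else {
        optim(v0, fobj, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-10))
      }
    }, error = function(e) NULL)
    if (is.null(op)) next
    converged <- TRUE
    w <- exp(c(0, op$par) - max(c(0, op$par)))
    w <- w / sum(w)
    if (op$value < best_score - 1e-12) {
      best_w <- w; best_score <- op$value
    }
  }
  if (!converged && n_restarts > 0L) {
    stop("weight optimization failed to converge from any start")
  }
  structure(list(weights = setNames(best_w, nms), score = best_score,
                 member_scores = setNames(corner_scores, nms),
                 alpha = alpha, penalty = penalty),
            class = "ensemble_weights")
}

#' @export
print.ensemble_weights <- function(x, ...) {
  cat("Optimized ensemble weights (mean 95% interval score",
      sprintf("%.4f):\n", x$score))
  print(round(x$weights, 3))
  invisible(x)
}

#' Combine member forecasts with convex weights
#'
#' Weighted quantile averaging per horizon at the median and the 80% and 95%
#' interval bounds, truncated at zero on the count scale.
#'
#' @param member_forecasts named list of [forecast_distribution()] objects
#'   sharing origin and horizons.
#' @param weights an [optimize_weights()] result or a bare named weight
#'   vector aligned to `member_forecasts`.
#' @return a `combined_forecast` data.frame (`horizon`, `median`, `lo80`,
#'   `up80`, `lo95`, `up95`).
#' @export
combine <- function(member_forecasts, weights) {
  w <- if (inherits(weights, "ensemble_weights")) weights$weights else weights
  if (length(w) != length(member_forecasts)) {
    stop("weight/member count mismatch")
  }
  if (!is.null(names(w)) && !is.null(names(member_forecasts))) {
    if (!setequal(names(w), names(member_forecasts))) {
      stop("weight names do not match member names")
    }
    w <- w[names(member_forecasts)]
  }
  w <- w / sum(w)
  ss <- lapply(member_forecasts, summary)
  H <- nrow(ss[[1L]])
  if (!all(vapply(ss, nrow, 1L) == H)) stop("horizon mismatch among members")
  count_scale <- any(vapply(member_forecasts, function(f) f$scale == "count",
                            TRUE))
  out <- data.frame(horizon = ss[[1L]]$horizon)
  for (colnm in c("median", "lo80", "up80", "lo95", "up95")) {
    v <- Reduce(`+`, Map(function(s, wi) wi * s[[colnm]], ss, w))
    out[[colnm]] <- if (count_scale) pmax(v, 0) else v
  }
  class(out) <- c("combined_forecast", "data.frame")
  out
}

#' Exhaustive simplex grid search for ensemble weights
#'
#' Brute-force reference for [optimize_weights()] on up to three members:
#' evaluates the mean interval score on a regular simplex grid.
#'
#' @param L,U members x observations matrices of interval bounds.
#' @param y observations.
#' @param step grid resolution (default 0.01).
#' @inheritParams interval_score
#' @return list with `weights` and `score`.
#' @export
grid_search_weights <- function(L, U, y, step = 0.01, alpha = 0.05,
                                penalty = "two_over_alpha") {
  M <- nrow(L)
  stopifnot(M %in% 2:3)
  g <- seq(0, 1, by = step)
  best_score <- Inf; best_w <- NULL
  for (w1 in g) {
    if (M == 2L) {
      w <- c(w1, 1 - w1)
      s <- mean_weighted_score(w, L, U, y, alpha, penalty)
      if (s < best_score) { best_score <- s; best_w <- w }
    } else {
      for (w2 in seq(0, 1 - w1, by = step)) {
        w <- c(w1, w2, 1 - w1 - w2)
        s <- mean_weighted_score(w, L, U, y, alpha, penalty)
        if (s < best_score) { best_score <- s; best_w <- w }
      }
    }
  }
  list(weights = best_w, score = best_score)
}

#' Write ensemble weights to a JSON file
#'
#' @param weights an [optimize_weights()] result.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "ensemble_weights"))
  jsonlite::write_json(list(weights = as.list(weights$weights),
                            score = weights$score,
                            alpha = weights$alpha,
                            penalty = weights$penalty),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
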