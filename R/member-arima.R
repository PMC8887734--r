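# Regression-ARIMA member on the seasonally adjusted series --------------

#' Forecast generic
#'
#' Dispatches on fitted member objects to produce a sample-path
#' [forecast_distribution()].
#' @param object a fitted member.
#' @param ... passed to methods.
#' @export
forecast <- function(object, ...) UseMethod("forecast")

try_arima <- function(y, order, xreg = NULL) {
  # do.call embeds the evaluated xreg in the call so predict() works later
  args <- list(y, order = order, include.mean = (order[2L] == 0L),
               method = "CSS-ML")
  if (!is.null(xreg)) args$xreg <- xreg
  tryCatch(suppressWarnings(do.call(arima, args)), error = function(e) NULL)
}

search_orders <- function(y, xreg = NULL, p_max = 3L, d_max = 1L,
                          q_max = 3L) {
  best <- NULL; best_bic <- Inf; best_order <- NULL
  for (d in 0:d_max) for (p in 0:p_max) for (q in 0:q_max) {
    f <- try_arima(y, c(p, d, q), xreg)
    if (is.null(f)) next
    b <- tryCatch(BIC(f), error = function(e) Inf)
    if (is.finite(b) && b < best_bic) {
      best <- f; best_bic <- b; best_order <- c(p, d, q)
    }
  }
  list(fit = best, bic = best_bic, order = best_order)
}

#' Fit the regression-ARIMA member
#'
#' Grid search over covariate subsets of size `0..max_predictors`, selecting
#' the subset and (p,d,q) orders that minimize in-sample BIC with Gaussian
#' innovations. To keep the grid tractable the search is staged: orders are
#' first tuned on the covariate-free model, all subsets are then compared at
#' those fixed orders, and orders are re-tuned for the winning subset.
#'
#' @param target seasonally adjusted training series (stationarity advisory;
#'   see [adf_test()]).
#' @param candidates a [select_lags()] predictor set aligned to `target`, or
#'   `NULL` for a covariate-free model.
#' @param max_predictors largest subset size considered (default 5).
#' @param p_max,d_max,q_max order-search bounds.
#' @return a `member_arima` fit: the `stats::arima` fit, selected predictor
#'   names, orders, BIC, coefficient table and residual sd.
#' @export
fit_arima_seasadj <- function(target, candidates = NULL, max_predictors = 5L,
                              p_max = 3L, d_max = 1L, q_max = 3L) {
  y <- as.numeric(target)
  if (any(!is.finite(y))) stop("target contains non-finite values")
  X <- if (!is.null(candidates)) candidates$x else NULL
  if (!is.null(X) && any(!is.finite(X))) stop("predictors contain non-finite values")

  stage1 <- search_orders(y, NULL, p_max, d_max, q_max)
  if (is.null(stage1$fit)) stop("no ARIMA order candidate converged")
  best_fit <- stage1$fit; best_bic <- stage1$bic
  best_subset <- character(0); best_order <- stage1$order

  if (!is.null(X) && ncol(X) >= 1L) {
    nms <- colnames(X)
    for (k in seq_len(min(max_predictors, ncol(X)))) {
      for (ss in as.data.frame(combn(nms, k), stringsAsFactors = FALSE)) {
        f <- try_arima(y, stage1$order, X[, ss, drop = FALSE])
        if (is.null(f)) next
        b <- tryCatch(BIC(f), error = function(e) Inf)
        if (is.finite(b) && b < best_bic) {
          best_fit <- f; best_bic <- b; best_subset <- ss
          best_order <- stage1$order
        }
      }
    }
    if (length(best_subset) > 0L) {
      stage3 <- search_orders(y, X[, best_subset, drop = FALSE],
                              p_max, d_max, q_max)
      if (!is.null(stage3$fit) && stage3$bic < best_bic) {
        best_fit <- stage3$fit; best_bic <- stage3$bic
        best_order <- stage3$order
      }
    }
  }

  cf <- coef(best_fit)
  se <- sqrt(pmax(diag(best_fit$var.coef), 0))
  structure(list(member = "arima_seasadj",
                 target_scale = "seasonally_adjusted",
                 fit = best_fit, order = best_order,
                 selected = best_subset, bic = best_bic,
                 coefficients = data.frame(term = names(cf),
                                           estimate = unname(cf),
                                           se = unname(se)),
                 sigma = sqrt(best_fit$sigma2),
                 y = y, candidates = candidates),
            class = c("member_arima", "tickcast_member"))
}

# Decompose an ARIMA member into simulation quantities ---------------------

arima_parts <- function(object) {
  if (!is.null(object$parts)) return(object$parts)  # hand-specified ARMA
  fit <- object$fit
  arma <- fit$arma
  p <- arma[1L]; q <- arma[2L]; d <- arma[6L]
  cf <- coef(fit)
  phi <- if (p > 0L) unname(cf[paste0("ar", 1:p)]) else numeric(0)
  theta <- if (q > 0L) unname(cf[paste0("ma", 1:q)]) else numeric(0)
  mu <- if ("intercept" %in% names(cf)) unname(cf[["intercept"]]) else 0
  bnames <- object$selected
  beta <- if (length(bnames)) unname(cf[bnames]) else numeric(0)
  y <- object$y
  z <- y - mu
  if (length(bnames)) {
    z <- z - as.numeric(object$candidates$x[, bnames, drop = FALSE] %*% beta)
  }
  w <- if (d > 0L) diff(z, differences = d) else z
  list(p = p, d = d, q = q, phi = phi, theta = theta, mu = mu, beta = beta,
       bnames = bnames, sigma = sqrt(fit$sigma2),
       eps = as.numeric(fit$residuals), z = z, w = w,
       var_coef = fit$var.coef)
}

# Per-path simulation state for the ARIMA member. Each of `n` trajectories
# carries the recent ARMA history (w values, innovations) and, when
# `coef_draws`, its own draw of the regression coefficients/intercept from
# their Gaussian sampling distribution.
arima_state_init <- function(object, n, coef_draws = TRUE) {
  pp <- arima_parts(object)
  W <- if (pp$p > 0L) {
    matrix(rep(tail(pp$w, pp$p), each = n), n, pp$p)  # col 1 = most recent
  } else matrix(0, n, 0)
  if (pp$p > 0L) W[] <- W[, rev(seq_len(pp$p)), drop = FALSE]
  E <- if (pp$q > 0L) {
    matrix(rep(rev(tail(pp$eps, pp$q)), each = n), n, pp$q)
  } else matrix(0, n, 0)
  Z <- if (pp$d > 0L) {
    dd <- vapply(seq_len(pp$d) - 1L, function(j) {
      if (j == 0L) tail(pp$z, 1L) else tail(diff(pp$z, differences = j), 1L)
    }, numeric(1))
    matrix(rep(dd, each = n), n, pp$d)  # last values of z, dz, ...
  } else matrix(0, n, 0)
  k <- length(pp$beta) + (pp$d == 0L)
  B <- NULL; MU <- rep(pp$mu, n)
  if (coef_draws && k > 0L && !is.null(pp$var_coef)) {
    nm <- c(pp$bnames, if (pp$d == 0L) "intercept")
    V <- pp$var_coef[nm, nm, drop = FALSE]
    V <- (V + t(V)) / 2
    ch <- tryCatch(chol(V + diag(1e-12, nrow(V))), error = function(e) NULL)
    mean_vec <- c(pp$beta, if (pp$d == 0L) pp$mu)
    if (!is.null(ch)) {
      draws <- matrix(rnorm(n * k), n, k) %*% ch
      draws <- sweep(draws, 2L, mean_vec, "+")
    } else {
      draws <- matrix(rep(mean_vec, each = n), n, k)
    }
    if (length(pp$bnames)) B <- draws[, seq_along(pp$bnames), drop = FALSE]
    if (pp$d == 0L) MU <- draws[, k]
  } else if (length(pp$beta)) {
    B <- matrix(rep(pp$beta, each = n), n, length(pp$beta))
  }
  list(kind = "arima", parts = pp, n = n, W = W, E = E, Z = Z, B = B,
       MU = MU)
}

# Advance every trajectory one step; xrow = named scaled regressor row (or
# NULL). Returns list(state, values) where values are the proposed next
# observations on the seasonally adjusted scale.
arima_state_step <- function(state, xrow = NULL, innov = NULL) {
  pp <- state$parts
  n <- state$n
  if (is.null(innov)) innov <- rnorm(n, 0, pp$sigma)
  w_new <- innov
  if (pp$p > 0L) w_new <- w_new + as.numeric(state$W %*% pp$phi)
  if (pp$q > 0L) w_new <- w_new + as.numeric(state$E %*% pp$theta)
  # integrate d times: Z column j holds the last value of the (j-1)th
  # difference of z (column 1 is z itself)
  if (pp$d > 0L) {
    inc <- w_new
    for (j in rev(seq_len(pp$d))) {
      state$Z[, j] <- state$Z[, j] + inc
      inc <- state$Z[, j]
    }
    z_new <- state$Z[, 1L]
  } else {
    z_new <- w_new
  }
  reg <- state$MU
  if (!is.null(state$B) && length(pp$bnames)) {
    xr <- xrow[pp$bnames]
    if (anyNA(xr)) stop("missing regressor values for: ",
                        paste(pp$bnames[is.na(xr)], collapse = ", "))
    reg <- reg + as.numeric(state$B %*% xr)
  }
  values <- z_new + reg
  if (pp$p > 0L) {
    state$W <- cbind(w_new, state$W[, -pp$p, drop = FALSE])
  }
  if (pp$q > 0L) {
    state$E <- cbind(innov, state$E[, -pp$q, drop = FALSE])
  }
  list(state = state, values = values)
}

# Replace each trajectory's most recent observed value with `obs` (used when
# conditioning on an assimilated observation is not wanted keeps history) --
# intentionally not done: the bootstrap filter keeps each particle's own path.

#' @describeIn fit_arima_seasadj simulate forecast sample paths.
#' @param object fitted member.
#' @param horizon fortnights ahead (>= 1).
#' @param n_paths sample trajectories (default 1000).
#' @param seed optional integer for reproducible paths.
#' @param persist_covariates carry last covariate values forward when a
#'   horizon exceeds a predictor's selected lag.
#' @param coef_draws include regression-coefficient sampling uncertainty.
#' @param ... unused.
#' @export
forecast.member_arima <- function(object, horizon, n_paths = 1000,
                                  seed = NULL, persist_covariates = FALSE,
                                  coef_draws = TRUE, ...) {
  stopifnot(horizon >= 1)
  run <- function() {
    xf <- if (length(object$selected)) {
      future_xreg(object$candidates, horizon, persist = persist_covariates,
                  vars = object$selected)
    } else NULL
    state <- arima_state_init(object, n_paths, coef_draws)
    paths <- matrix(0, n_paths, horizon)
    for (h in seq_len(horizon)) {
      st <- arima_state_step(state, xrow = if (!is.null(xf)) xf[h, ] else NULL)
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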