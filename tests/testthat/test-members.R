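# Forecast members: recovery, contracts, forecast distributions

test_that("ARIMA member recovers a known regressor among noise", {
  set.seed(301)
  n <- 300L
  X <- matrix(rnorm(n * 3L), n, dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- as.numeric(arima.sim(list(ar = 0.5, ma = 0.3), n)) + 1.0 * X[, "x1"]
  fit <- fit_arima_seasadj(y, as_candidates(X), p_max = 2L, q_max = 2L)
  expect_true("x1" %in% fit$selected)
  b <- fit$coefficients[fit$coefficients$term == "x1", ]
  expect_lt(abs(b$estimate - 1), 2 * b$se)
})

test_that("covariate-free ARIMA fits and a duplicated regressor never lowers BIC", {
  set.seed(302)
  y <- as.numeric(arima.sim(list(ar = 0.6), 150))
  f0 <- fit_arima_seasadj(y, NULL, p_max = 2L, q_max = 1L)
  expect_true(is.finite(f0$bic))
  expect_identical(f0$selected, character(0))

  x1 <- rnorm(150)
  y2 <- y + x1
  f1 <- tickcast:::try_arima(y2, c(1L, 0L, 0L), cbind(x1 = x1))
  f2 <- tickcast:::try_arima(y2, c(1L, 0L, 0L), cbind(x1 = x1, dup = x1))
  if (!is.null(f2)) expect_gte(BIC(f2), BIC(f1) - 1e-6)
})

test_that("forecast paths are seed-deterministic with ordered intervals", {
  p <- fixture_pipeline()
  fit <- fit_arima_seasadj(p$sa, p$lp, p_max = 1L, q_max = 1L)
  a <- forecast(fit, 6L, n_paths = 200, seed = 99, persist_covariates = TRUE)
  b <- forecast(fit, 6L, n_paths = 200, seed = 99, persist_covariates = TRUE)
  expect_identical(a$paths, b$paths)
  s <- summary(a)
  bounds <- as.matrix(s[, c("lo95", "lo80", "median", "up80", "up95")])
  expect_true(all(diff(t(bounds)) >= 0))
})

test_that("simulated ARMA intervals match the closed-form Gaussian forecast", {
  set.seed(303)
  y <- as.numeric(arima.sim(list(ar = 0.7, ma = 0.2), 400))
  fit <- fit_arima_seasadj(y, NULL, p_max = 2L, q_max = 2L)
  fc <- forecast(fit, 8L, n_paths = 4000, seed = 7, coef_draws = FALSE)
  pr <- predict(fit$fit, n.ahead = 8L)
  s <- summary(fc)
  want_up <- as.numeric(pr$pred + qnorm(0.975) * pr$se)
  want_lo <- as.numeric(pr$pred - qnorm(0.975) * pr$se)
  expect_lt(max(abs(s$up95 - want_up)), 0.15 * max(pr$se))
  expect_lt(max(abs(s$lo95 - want_lo)), 0.15 * max(pr$se))
})

test_that("nominal ARIMA intervals cover draws from the true model", {
  set.seed(304)
  phi <- 0.6
  y <- as.numeric(arima.sim(list(ar = phi), 300))
  fit <- fit_arima_seasadj(y, NULL, p_max = 1L, q_max = 0L)
  fc <- forecast(fit, 6L, n_paths = 2000, seed = 5)
  s <- summary(fc)
  hits <- 0L; total <- 0L
  for (r in 1:50) {
    x <- y[300]
    for (h in 1:6) {
      x <- phi * x + rnorm(1)
      hits <- hits + (x >= s$lo95[h] && x <= s$up95[h])
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.85)
})

test_that("GARCH member concentrates volatility terms near zero on homoskedastic data", {
  set.seed(305)
  n <- 150L
  X <- matrix(rnorm(n), n, 1L, dimnames = list(NULL, "x_null"))
  y <- as.numeric(arima.sim(list(ma = c(0.4, 0.2)), n))
  fit <- fit_garch_seasadj(y, as_candidates(X), chains = 2L, n_iter = 500L)
  a1 <- mean(fit$draws[, "a1"]); a2 <- mean(fit$draws[, "a2"])
  expect_lt(a1, 0.25)
  expect_lt(a2, 0.25)
  # the null predictor's 95% credible interval covers zero
  ci <- fit$coefficients[fit$coefficients$term == "x_null", ]
  expect_true(ci$lo95 <= 0 && ci$up95 >= 0)
  # no-information case: long-horizon predictive mean ~ unconditional mean
  fit0 <- fit_garch_seasadj(y, NULL, chains = 2L, n_iter = 400L)
  fc <- forecast(fit0, 20L, n_paths = 1500, seed = 1)
  expect_lt(abs(mean(fc$paths[, 20L]) - mean(y)), 3 * sd(y) / sqrt(n))
})

test_that("GAM member honours the cyclic constraint, shrinks null predictors and recovers phi", {
  set.seed(306)
  n <- 264L
  fn <- rep(1:24, length.out = n)
  mu <- exp(log(3) + 1.1 * sin(2 * pi * fn / 24) + 0.4 * sin(pi * seq_len(n) / n))
  counts <- fortnight_series(rnbinom(n, mu = mu, size = 2))
  X <- matrix(rnorm(n), n, 1L, dimnames = list(NULL, "pure_noise"))
  fit <- fit_gam_raw(counts, as_candidates(X))
  # phi within 50% relative error
  expect_lt(abs(fit$phi - 2) / 2, 0.5)
  # the uninformative predictor's shrinkage smooth has edf ~ 0
  edf_noise <- fit$edf$edf[grepl("pure_noise", fit$edf$term)]
  expect_lt(edf_noise, 0.5)
  # cyclic seasonal effect is continuous across the year boundary
  nd <- data.frame(year_cont = 5, fortnight = c(0.51, 24.49), pure_noise = 0)
  terms <- predict(fit$fit, newdata = nd, type = "terms")
  seas_col <- grep("fortnight", colnames(terms))
  expect_lt(abs(diff(terms[, seas_col])), 0.05)
  expect_error(fit_gam_raw(fortnight_series(rep(0, 264))), "all-zero")
})

test_that("GAM forecasts are nonnegative integer-valued count paths", {
  p <- fixture_pipeline()
  fit <- fit_gam_raw(p$split$train, p$lp)
  fc <- forecast(fit, 4L, n_paths = 200, seed = 3, persist_covariates = TRUE)
  expect_identical(fc$scale, "count")
  expect_true(all(fc$paths >= 0))
  expect_true(all(fc$paths == round(fc$paths)))
})

test_that("deviance ranking puts a shifted copy of the target first", {
  p <- fixture_pipeline()
  y <- p$split$train
  z <- log1p(as.numeric(y))
  set.seed(307)
  X <- cbind(copy_of_target = as.numeric(scale(z)),
             noise1 = rnorm(length(z)), noise2 = rnorm(length(z)),
             noise3 = rnorm(length(z)))
  fit <- fit_prophet_raw(y, as_candidates(X), n_predictors = 1L)
  expect_identical(fit$selected, "copy_of_target")
})

test_that("a noiseless linear trend needs no changepoints", {
  n <- 264L
  z <- 0.3 + 1.5 * seq_len(n) / n                 # linear on the log1p scale
  counts <- fortnight_series(expm1(z))
  fit <- fit_prophet_raw(counts)
  expect_lt(max(abs(fit$delta)), 0.05)
})

test_that("prophet-style forecasts live on the truncated count scale", {
  p <- fixture_pipeline()
  fit <- fit_prophet_raw(p$split$train, p$lp)
  expect_identical(length(fit$selected), 3L)
  fc <- forecast(fit, 4L, n_paths = 300, seed = 11, persist_covariates = TRUE)
  expect_identical(fc$scale, "count")
  expect_true(all(fc$paths >= 0))
  expect_warning(fit_prophet_raw(p$split$train,
                                 as_candidates(matrix(rnorm(225 * 2), 225,
                                                      dimnames = list(NULL, c("a", "b")))),
                                 n_predictors = 3L),
                 "fewer")
})

test_that("outcome-scale conversion adds pathwise and truncates at zero", {
  paths <- matrix(c(-2, 1, 4), 3, 2)
  fc <- forecast_distribution(paths, member = "m",
                              scale = "seasonally_adjusted")
  zero <- forecast_distribution(matrix(0, 3, 2), member = "s",
                                scale = "seasonal_component")
  out <- to_outcome_scale(fc, zero)
  expect_equal(out$paths, pmax(paths, 0))
  seas <- forecast_distribution(matrix(1, 3, 2), member = "s",
                                scale = "seasonal_component")
  out2 <- to_outcome_scale(fc, seas)
  expect_equal(out2$paths[1L, 1L], 0)      # -2 + 1 floors at zero
  expect_equal(out2$paths[3L, 1L], 5)
  # adding then subtracting the same seasonal paths recovers the positives
  sub <- forecast_distribution(out2$paths - 1, member = "m",
                               scale = "seasonally_adjusted")
  expect_equal(sub$paths[3L, ], paths[3L, ] + 0)
  bad <- forecast_distribution(matrix(0, 3, 3), member = "s",
                               scale = "seasonal_component")
  expect_error(to_outcome_scale(fc, bad), "horizon mismatch")
})
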