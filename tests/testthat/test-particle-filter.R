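# Sequential Monte Carlo filter: weights, resampling, exactness

test_that("effective sample size follows 1 / sum(w^2)", {
  expect_equal(effective_sample_size(rep(1, 100)), 100)
  expect_equal(effective_sample_size(c(1, rep(0, 99))), 1)
  expect_equal(effective_sample_size(c(0.5, 0.5, rep(0, 98))), 2)
  expect_error(effective_sample_size(rep(0, 10)), "zero")
})

test_that("initialization gives uniform weights and deterministic states", {
  m <- arma_member(phi = 0.7, sigma = 1)
  a <- init_particles(m, n = 500L, seed = 5)
  b <- init_particles(m, n = 500L, seed = 5)
  expect_identical(a$state, b$state)
  expect_equal(effective_sample_size(a), 500)
  expect_true(all(particle_weights(a) == 1 / 500))
})

test_that("particle mean trajectory tracks the member forecast", {
  p <- fixture_pipeline()
  fit <- fit_arima_seasadj(p$sa, NULL, p_max = 1L, q_max = 1L)
  fc <- forecast(fit, 6L, n_paths = 4000, seed = 8)
  ps <- init_particles(fit, n = 4000L, seed = 8)
  pffc <- pf_forecast(ps, 6L, seed = 8)
  m1 <- summary(fc)$median
  m2 <- summary(pffc)$median
  expect_lt(max(abs(m1 - m2)), 4 * fit$sigma / sqrt(1000))
})

test_that("equal proposals leave weights uniform; sharp likelihoods concentrate them", {
  m <- arma_member(phi = 0, sigma = 1e-12, z_last = 2)
  ps <- init_particles(m, n = 100L,
                       cfg = filter_config(obs_noise_sd = 1), seed = 1)
  ps <- assimilate(ps, 2.5)
  expect_lt(diff(range(particle_weights(ps))), 1e-12)

  # hand-planted proposals: one particle at the observation, rest far away
  m2 <- arma_member(phi = 1, sigma = 1e-9)
  ps2 <- init_particles(m2, n = 50L,
                        cfg = filter_config(obs_noise_sd = 0.1), seed = 2)
  ps2$state$W[, 1] <- c(3, rep(10, 49))
  ps2 <- assimilate(ps2, 3)
  expect_gt(particle_weights(ps2)[1L], 1 - 1e-10)
  expect_error(assimilate(ps2, NA_real_), "finite")
})

test_that("assimilation shrinks the posterior mean toward the observation", {
  m <- arma_member(phi = 1, sigma = 0.5, z_last = 0)
  ps <- init_particles(m, n = 5000L,
                       cfg = filter_config(obs_noise_sd = 0.5,
                                           mutation_sd = 0), seed = 3)
  with_seed <- tickcast:::with_seed
  ps <- with_seed(4, assimilate(ps, 2))
  post_mean <- sum(particle_weights(ps) * particle_values(ps))
  # linear-Gaussian toy: prior N(0, 0.25), likelihood N(2, 0.25) -> posterior
  # mean 1
  expect_lt(abs(post_mean - 1), 0.1)
  expect_gt(post_mean, 0.5)
})

test_that("without resampling the filter is exact sequential importance sampling", {
  m <- arma_member(phi = 0.6, sigma = 1)
  ps <- init_particles(m, n = 200L,
                       cfg = filter_config(obs_noise_sd = 1, mutation_sd = 0,
                                           ess_threshold_fraction = 1e-9),
                       seed = 6)
  obs <- c(0.5, -0.2, 1.1, 0.3)
  manual <- rep(0, 200L)
  set.seed(7)
  for (o in obs) {
    ps <- assimilate(ps, o)
    manual <- manual + dnorm(o, particle_values(ps), 1, log = TRUE)
  }
  expect_equal(ps$log_w, manual, tolerance = 1e-12)
})

test_that("resampling triggers on degeneracy, resets weights and respects expectation", {
  m <- arma_member(phi = 0.5, sigma = 1)
  ps <- init_particles(m, n = 400L, cfg = filter_config(obs_noise_sd = 1),
                       seed = 9)
  expect_identical(maybe_resample(ps)$log_w, ps$log_w)  # ESS = N, untouched

  ps_deg <- ps
  ps_deg$log_w <- c(0, rep(-1e6, 399L))
  out <- tickcast:::with_seed(10, maybe_resample(ps_deg))
  expect_equal(effective_sample_size(out), 400)

  # multinomial expectation: weights (0.9, 0.1, 0, ...) copy particle 1
  # about 0.9 N times
  ps2 <- init_particles(m, n = 5000L,
                        cfg = filter_config(obs_noise_sd = 1,
                                            mutation_sd = 0), seed = 11)
  ps2$state$W[, 1] <- seq_len(5000L)
  ps2$log_w <- log(c(0.9, 0.1, rep(1e-300, 4998L)))
  out2 <- tickcast:::with_seed(12, maybe_resample(ps2))
  frac1 <- mean(out2$state$W[, 1] == 1)
  expect_lt(abs(frac1 - 0.9), 3 * sqrt(0.9 * 0.1 / 5000))
})

test_that("particle filter matches the exact Kalman filter on a linear-Gaussian toy", {
  a <- 0.8; q <- 0.25; r <- 0.16
  set.seed(13)
  Tn <- 20L
  x <- numeric(Tn); x[1] <- rnorm(1, 0, sqrt(q / (1 - a^2)))
  for (t in 2:Tn) x[t] <- a * x[t - 1] + rnorm(1, 0, sqrt(q))
  y <- x + rnorm(Tn, 0, sqrt(r))
  kal <- kalman_ar1(y, a, q, r)
  for (N in c(500L, 5000L)) {
    m <- arma_member(phi = a, sigma = sqrt(q))
    ps <- init_particles(m, n = N,
                         cfg = filter_config(obs_noise_sd = sqrt(r),
                                             mutation_sd = 0), seed = 14)
    set.seed(15)
    ps$state$W[, 1] <- rnorm(N, 0, sqrt(q / (1 - a^2)))
    pm <- numeric(Tn)
    set.seed(16)
    for (t in seq_len(Tn)) {
      ps <- assimilate(ps, y[t])
      pm[t] <- sum(particle_weights(ps) * particle_values(ps))
      ps <- maybe_resample(ps)
    }
    # Monte-Carlo error shrinks with N
    tol <- 3 * sqrt(mean(kal$var)) / sqrt(N / 10)
    expect_lt(max(abs(pm - kal$mean)), tol)
  }
})

test_that("weighted quantiles with uniform weights equal unweighted quantiles", {
  set.seed(17)
  x <- rnorm(500)
  expect_equal(weighted_quantile(x, rep(1, 500), c(0.1, 0.5, 0.9)),
               as.numeric(quantile(x, c(0.1, 0.5, 0.9), type = 1)),
               tolerance = 1e-12)
})

test_that("pf forecasts keep interval ordering and use the seasonal paths", {
  m <- arma_member(phi = 0.7, sigma = 1)
  ps <- init_particles(m, n = 1000L, seed = 18)
  seas <- forecast_distribution(matrix(5, 1000, 4), member = "s",
                                scale = "seasonal_component")
  fc <- pf_forecast(ps, 4L, seas, seed = 19)
  expect_identical(fc$scale, "count")
  s <- summary(fc)
  bounds <- as.matrix(s[, c("lo95", "lo80", "median", "up80", "up95")])
  expect_true(all(diff(t(bounds)) >= 0))
  expect_true(all(fc$paths >= 0))
  expect_error(pf_forecast(ps, 0L), "horizon")
})

test_that("clinic-level adaptation initializes noisier clinics with larger error scales", {
  p <- fixture_pipeline()
  fit <- fit_arima_seasadj(p$sa, NULL, p_max = 1L, q_max = 1L)
  set.seed(20)
  n <- length(p$split$train)
  base <- pmax(round(as.numeric(p$split$train) / 2), 0)
  quiet <- fortnight_series(base + rpois(n, 0.2), start = c(2007L, 1L))
  noisy <- fortnight_series(base + rpois(n, 4), start = c(2007L, 1L))
  res <- adapt_to_subseries(list(arima_seasadj = fit),
                            list(quiet = quiet, noisy = noisy),
                            n = 300L, seed = 21)
  expect_gt(res$noisy$obs_noise_sd, res$quiet$obs_noise_sd)
  expect_equal(sum(particle_weights(res$quiet$particles$arima_seasadj)), 1,
               tolerance = 1e-9)
  short <- fortnight_series(rpois(30, 2))
  expect_error(adapt_to_subseries(list(a = fit), list(s = short)),
               "two seasonal cycles")
})
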