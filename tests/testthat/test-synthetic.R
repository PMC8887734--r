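# Synthetic-data generator: determinism, moments, recoverable structure

test_that("covariate simulation is deterministic and refuses tiny horizons", {
  cfg <- sim_config(n_years = 3L, rng_seed = 7L)
  a <- simulate_covariates(cfg)
  b <- simulate_covariates(cfg)
  expect_identical(a, b)
  expect_error(simulate_covariates(sim_config(n_years = 1L)),
               "n_years")
})

test_that("zero noise gives exactly periodic climate series", {
  cfg <- sim_config(n_years = 4L, noise_scale = 0, rng_seed = 3L)
  cov <- simulate_covariates(cfg)
  x <- cov$max_temperature
  expect_equal(x[seq_len(length(x) - 24L)], x[-seq_len(24L)],
               tolerance = 1e-12)
  r <- cov$rainfall
  expect_equal(r[seq_len(length(r) - 24L)], r[-seq_len(24L)],
               tolerance = 1e-12)
})

test_that("AR(1) noise reproduces its theoretical lag-1 autocorrelation", {
  set.seed(101)
  x <- tickcast:::ar1_series(500L, 0.8, 1)
  r1 <- acf(x, lag.max = 1L, plot = FALSE)$acf[2L]
  # Monte-Carlo tolerance: sd of the lag-1 ACF estimate is roughly
  # sqrt((1 - rho^2)/n) ~ 0.027 here
  expect_lt(abs(r1 - 0.8), 3 * sqrt((1 - 0.8^2) / 500))
})

test_that("case simulation is seed-deterministic and conserves records", {
  cfg <- sim_config(n_years = 3L, duplicate_rate = 0,
                    false_positive_rate = 0, rng_seed = 11L)
  cov <- simulate_covariates(cfg)
  s1 <- simulate_cases(cfg, cov)
  s2 <- simulate_cases(cfg, cov)
  expect_identical(s1$cases, s2$cases)
  # no duplicates, no false positives: records equal the drawn counts
  expect_identical(nrow(s1$cases), as.integer(sum(s1$truth$count)))
  expect_identical(s1$n_duplicates, 0L)
})

test_that("unknown covariate effect names are rejected", {
  cfg <- sim_config(n_years = 3L,
                    covariate_effects = list(bogus = list(lag = 1L,
                                                          beta = 1)))
  expect_error(simulate_cases(cfg), "unknown predictor")
})

test_that("fortnight means track baseline x seasonal factor without effects", {
  amps <- default_seasonal_amplitudes()
  cfg <- sim_config(n_years = 40L, baseline = 2, seasonal_amplitudes = amps,
                    trend_knots = cbind(c(0, 1), c(0, 0)),
                    covariate_effects = list(), duplicate_rate = 0,
                    false_positive_rate = 0, rng_seed = 5L)
  sim <- simulate_cases(cfg)
  got <- tapply(sim$truth$count, sim$truth$fortnight, mean)
  want <- 2 * amps
  # per-fortnight Monte-Carlo error: sd ~ sqrt((mu + mu^2/phi)/40)
  sds <- sqrt((want + want^2 / cfg$phi) / 40)
  expect_true(all(abs(got - want) < 4 * sds))
})

test_that("negative-binomial draws obey the mean-variance relation", {
  # var = mu + mu^2 / phi; and the Poisson limit as phi grows
  set.seed(21)
  for (case in list(c(mu = 4, phi = 2), c(mu = 10, phi = 0.8))) {
    x <- rnbinom(20000L, mu = case[["mu"]], size = case[["phi"]])
    want <- case[["mu"]] + case[["mu"]]^2 / case[["phi"]]
    expect_lt(abs(var(x) - want) / want, 0.1)
  }
  cfg <- sim_config(n_years = 30L, phi = 1e6, covariate_effects = list(),
                    trend_knots = cbind(c(0, 1), c(0, 0)),
                    duplicate_rate = 0, false_positive_rate = 0,
                    rng_seed = 13L)
  sim <- simulate_cases(cfg)
  one_fn <- sim$truth$count[sim$truth$fortnight == 20L]
  expect_lt(abs(var(one_fn) / mean(one_fn) - 1), 0.5)  # Poisson limit
})

test_that("an injected lagged covariate effect is recoverable", {
  cfg <- sim_config(n_years = 20L, baseline = 6,
                    seasonal_amplitudes = rep(1, 24),
                    trend_knots = cbind(c(0, 1), c(0, 0)),
                    covariate_effects = list(SOI = list(lag = 3L,
                                                        beta = 1.0)),
                    phi = 20, duplicate_rate = 0, false_positive_rate = 0,
                    rng_seed = 17L)
  cov <- simulate_covariates(cfg)
  sim <- simulate_cases(cfg, cov)
  soi <- cov$SOI[cov$year >= cfg$start_year]
  cc <- vapply(1:6, function(k) {
    n <- nrow(sim$truth)
    cor(soi[seq_len(n - k)], sim$truth$count[(k + 1):n])
  }, numeric(1))
  expect_identical(which.max(abs(cc)), 3L)
})

test_that("simulation files round-trip through CSV", {
  cfg <- sim_config(n_years = 2L, rng_seed = 2L)
  cov <- simulate_covariates(cfg)
  sim <- simulate_cases(cfg, cov)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, cov, dir)
  cases <- read_cases(paths[1L])
  expect_identical(nrow(cases), nrow(sim$cases))
  expect_s3_class(cases$admission_date, "Date")
  cov2 <- read_covariates(paths[2L])
  expect_equal(cov2$SOI, cov$SOI, tolerance = 1e-12)
})
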