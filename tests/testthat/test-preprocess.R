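# Dedup, binning, STL, predictor engineering

rec <- function(dates, clinic = "c1", species = "dog",
                class = "confirmed") {
  data.frame(admission_date = as.Date(dates), clinic_id = clinic,
             species = species, record_class = class,
             stringsAsFactors = FALSE)
}

test_that("dedup drops re-recordings inside the window and keeps the rest", {
  r <- rec(c("2010-03-01", "2010-03-04"))
  expect_identical(nrow(dedupe_cases(r, 14L)), 1L)
  r2 <- rec(c("2010-03-01", "2010-03-21"))
  expect_identical(nrow(dedupe_cases(r2, 14L)), 2L)
  # different streams never interact
  r3 <- rbind(rec("2010-03-01"), rec("2010-03-02", clinic = "c2"),
              rec("2010-03-03", species = "cat"))
  expect_identical(nrow(dedupe_cases(r3, 14L)), 3L)
  expect_error(dedupe_cases(r, -1L), "nonnegative")
})

test_that("dedup is idempotent and matches generator bookkeeping at low intensity", {
  # sparse caseload: accidental within-window pairs are absent for this seed,
  # so the removed records are exactly the injected re-recordings
  cfg <- sim_config(n_years = 4L, baseline = 0.1, duplicate_rate = 0.3,
                    seasonal_amplitudes = rep(1, 24),
                    false_positive_rate = 0, covariate_effects = list(),
                    clinic_ids = paste0("clinic_", 1:8), rng_seed = 31L)
  sim <- simulate_cases(cfg)
  d1 <- dedupe_cases(sim$cases, 14L)
  expect_identical(nrow(sim$cases) - nrow(d1), sim$n_duplicates)
  d2 <- dedupe_cases(d1, 14L)
  expect_identical(d1, d2)
})

test_that("fortnight binning uses the day-15/16 boundary and conserves counts", {
  r <- rec(c("2011-01-15", "2011-01-16", "2011-02-28", "2011-12-31"))
  s <- bin_fortnights(r, 2011L, 2011L)
  expect_identical(length(s), 24L)
  df <- as.data.frame(s)
  expect_identical(df$value[df$fortnight == 1L], 1)
  expect_identical(df$value[df$fortnight == 2L], 1)
  expect_identical(df$value[df$fortnight == 4L], 1)   # Feb 28 is in bin 2
  expect_identical(df$value[df$fortnight == 24L], 1)
  expect_identical(sum(s), 4)
  expect_identical(length(bin_fortnights(r, 2011L, 2021L)), 264L)
  empty <- bin_fortnights(rec("2011-01-01")[0, ], 2011L, 2012L)
  expect_identical(sum(empty), 0)
  expect_identical(length(empty), 48L)
  expect_error(bin_fortnights(r, 2012L, 2012L), "outside")
})

test_that("STL components always sum to the input", {
  p <- fixture_pipeline()
  dec <- p$dec
  resid <- as.numeric(dec$seasonal) + as.numeric(dec$trend) +
    as.numeric(dec$remainder) - as.numeric(p$split$train)
  expect_lt(max(abs(resid)), 1e-8)
})

test_that("STL resolves constants and pure seasonal signals correctly", {
  const <- fortnight_series(rep(5, 96))
  dc <- stl_decompose(const)
  expect_lt(max(abs(as.numeric(dc$trend) - 5)), 1e-6)
  expect_lt(max(abs(as.numeric(dc$seasonal))), 1e-6)
  expect_lt(max(abs(as.numeric(dc$remainder))), 1e-6)

  tt <- seq_len(240)
  sine <- fortnight_series(sin(2 * pi * tt / 24))
  ds <- stl_decompose(sine)
  energy <- function(x) sum(as.numeric(x)^2)
  expect_gt(energy(ds$seasonal) / energy(sine), 0.95)
  expect_lt(energy(ds$remainder) / energy(sine), 0.02)

  expect_error(stl_decompose(fortnight_series(rnorm(40))), "two seasonal")
})

test_that("seasonal adjustment is exactly the trend-plus-remainder inverse", {
  p <- fixture_pipeline()
  sa <- seasonally_adjust(p$dec)
  expect_lt(max(abs(as.numeric(sa) + as.numeric(p$dec$seasonal) -
                      as.numeric(p$split$train))), 1e-8)
  expect_lt(var(as.numeric(sa)), var(as.numeric(p$split$train)))
})

test_that("moist vegetation index follows the configured convention", {
  expect_identical(moist_vegetation(10, 2, 0.3, 0.2), -10)
  expect_identical(moist_vegetation(0, 5, 0.4, 0.4), 0)
  expect_identical(moist_vegetation(7, 3, 0, 0), 0)
  expect_identical(moist_vegetation(10, 2, 0.3, 0.2, convention = "deficit"),
                   4)
  expect_error(moist_vegetation(1:3, 1:2, 1:3, 1:3), "aligned")
})

test_that("quarterly anomalies centre, localize and stay linear", {
  fn <- rep(1:24, 4)
  yr <- rep(2001:2004, each = 24L)
  x <- rep(sin(1:24), 4)                       # identical every year
  expect_lt(max(abs(quarterly_anomaly(x, fn, yr))), 1e-12)

  set.seed(4)
  z <- rnorm(96)
  a <- quarterly_anomaly(z, fn, yr)
  q <- tickcast:::quarter_of_fortnight(fn)
  expect_lt(max(abs(tapply(a, q, mean))), 1e-12)  # per-quarter mean zero

  # shifting one year's quarter by +2 moves its anomalies by 2 * (1 - 1/4)
  z2 <- z
  bump <- fn %in% 1:6 & yr == 2002L
  z2[bump] <- z2[bump] + 2
  a2 <- quarterly_anomaly(z2, fn, yr)
  expect_equal(unique(round(a2[bump] - a[bump], 10)), 2 * (1 - 1 / 4))

  # linearity under a shared climatology
  w <- rnorm(96)
  expect_equal(quarterly_anomaly(z + w, fn, yr),
               quarterly_anomaly(z, fn, yr) + quarterly_anomaly(w, fn, yr),
               tolerance = 1e-12)
  expect_error(quarterly_anomaly(z[1:30], fn[1:30], yr[1:30]),
               "two full years")
})

test_that("collinearity pruning honours threshold and priority", {
  set.seed(8)
  x <- rnorm(300)
  cand <- data.frame(a = x, b = x, c = rnorm(300))
  expect_identical(prune_collinear(cand), c("a", "c"))
  expect_identical(prune_collinear(cand, priority = c("b", "a", "c")),
                   c("b", "c"))
  ind <- as.data.frame(matrix(rnorm(300 * 4), 300))
  expect_identical(prune_collinear(ind), names(ind))
  one <- prune_collinear(data.frame(a = x, b = x + rnorm(300, 0, 2),
                                    c = rnorm(300)), threshold = 0)
  expect_identical(length(one), 1L)
})

test_that("lag selection recovers constructed lags and scales to unit sd", {
  set.seed(9)
  n <- 200L; lead <- 6L
  target <- as.numeric(arima.sim(list(ar = 0.6), n))
  covs <- data.frame(
    shifted = c(rnorm(lead - 3L), target, rnorm(3L)),  # target shifted by 3
    noise = rnorm(n + lead))
  covs$shifted <- covs$shifted + rnorm(n + lead, 0, 0.05)
  lp <- select_lags(covs, target, max_lag = 6L)
  expect_identical(unname(lp$lag["shifted"]), 3L)
  expect_false(lp$weak[["shifted"]])
  expect_true(lp$weak[["noise"]])
  expect_equal(unname(apply(lp$x, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_error(select_lags(data.frame(z = rep(1, n + lead)), target),
               "zero-variance")
  expect_error(select_lags(covs[1:(n + 2L), , drop = FALSE], target),
               "max_lag")
})

test_that("future regressor rows respect lag availability", {
  p <- fixture_pipeline()
  lp <- p$lp
  min_lag <- min(lp$lag)
  xf <- future_xreg(lp, min_lag)
  expect_identical(dim(xf), c(as.integer(min_lag), length(lp$names)))
  expect_error(future_xreg(lp, min_lag + 1L), "persist")
  xf2 <- future_xreg(lp, min_lag + 1L, persist = TRUE)
  expect_false(anyNA(xf2))
  # an extended engineered table (observations kept arriving) removes the cap
  n_obs <- lp$lead_in + lp$n
  eng <- engineer_covariates(p$cov,
                             climatology = seq_len(nrow(p$cov)) <= n_obs)
  xf3 <- future_xreg(lp, min_lag + 1L, covariates = eng)
  expect_false(anyNA(xf3))
  # non-anomaly predictors agree exactly with the training-table rows;
  # anomaly columns are only finalized once their calendar quarter completes
  stable <- grep("anomaly", lp$names, value = TRUE, invert = TRUE)
  expect_equal(future_xreg(lp, min_lag, covariates = eng)[, stable],
               future_xreg(lp, min_lag)[, stable], tolerance = 1e-12)
})
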