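# Shared fixtures, built once per session and cached ----------------------

.fx <- new.env(parent = emptyenv())

# default-conditions simulation carried through the full preprocessing stack
fixture_pipeline <- function() {
  if (is.null(.fx$pipe)) {
    cfg <- sim_config(rng_seed = 42L)
    cov <- simulate_covariates(cfg)
    sim <- simulate_cases(cfg, cov)
    counts <- bin_fortnights(dedupe_cases(sim$cases), 2007L, 2017L)
    sp <- train_test_split(counts)
    dec <- stl_decompose(sp$train)
    sa <- seasonally_adjust(dec)
    lp <- prepare_predictors(cov[1:(6L + length(sp$train)), ], sa)
    .fx$pipe <- list(cfg = cfg, cov = cov, sim = sim, counts = counts,
                     split = sp, dec = dec, sa = sa, lp = lp)
  }
  .fx$pipe
}

# minimal predictor-set wrapper for fit-only tests (columns already lagged
# and scaled)
as_candidates <- function(X) {
  X <- as.matrix(X)
  structure(list(x = X, names = colnames(X)), class = "lagged_predictors")
}

# hand-specified ARMA member (no stats::arima fit behind it); used to drive
# the particle filter on exactly known dynamics
arma_member <- function(phi = numeric(0), theta = numeric(0), d = 0L,
                        mu = 0, sigma = 1, z_last = 0, eps_last = 0) {
  p <- length(phi); q <- length(theta)
  structure(list(
    member = "arima_seasadj", target_scale = "seasonally_adjusted",
    selected = character(0), candidates = NULL, sigma = sigma, y = z_last,
    parts = list(p = p, d = as.integer(d), q = q, phi = phi, theta = theta,
                 mu = mu, beta = numeric(0), bnames = character(0),
                 sigma = sigma, eps = rep(eps_last, max(q, 1L)),
                 z = rep(z_last, max(p, d, 1L)),
                 w = rep(z_last, max(p, 1L)), var_coef = NULL)),
    class = c("member_arima", "tickcast_member"))
}

# exact scalar Kalman filter for the AR(1)-plus-noise model
# x_t = a x_{t-1} + N(0, q);  y_t = x_t + N(0, r);  x_1 ~ N(0, q/(1-a^2))
kalman_ar1 <- function(y, a, q, r) {
  Tn <- length(y)
  m <- 0; P <- 0
  means <- numeric(Tn); vars <- numeric(Tn)
  for (t in seq_len(Tn)) {
    if (t == 1L) { mp <- 0; Pp <- q / (1 - a^2) }
    else { mp <- a * m; Pp <- a^2 * P + q }
    K <- Pp / (Pp + r)
    m <- mp + K * (y[t] - mp)
    P <- (1 - K) * Pp
    means[t] <- m; vars[t] <- P
  }
  list(mean = means, var = vars)
}
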