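# Interval scoring and weight optimization

test_that("interval score reproduces hand-evaluated cases", {
  expect_identical(interval_score(2, 10, 5), 8)
  expect_identical(interval_score(2, 10, 12, alpha = 0.05,
                                  penalty = "two_over_alpha"), 88)
  expect_equal(interval_score(2, 10, 12, alpha = 0.05,
                              penalty = "two_times_alpha"), 8.2)
  # low-side penalty mirrors the high side
  expect_identical(interval_score(2, 10, 0), 8 + 40 * 2)
  expect_error(interval_score(10, 2, 5), "lower > upper")
})

test_that("interval score is translation equivariant", {
  set.seed(401)
  for (i in 1:20) {
    l <- rnorm(1); u <- l + rexp(1); y <- rnorm(1, l, 3); c0 <- rnorm(1, 0, 10)
    expect_equal(interval_score(l, u, y),
                 interval_score(l + c0, u + c0, y + c0), tolerance = 1e-9)
  }
})

test_that("weighted intervals average bounds convexly", {
  w <- weighted_interval(c(0, 2), c(2, 4), c(0.5, 0.5))
  expect_equal(w, list(lower = 1, upper = 3))
  one <- weighted_interval(c(1, 5), c(2, 9), c(1, 0))
  expect_equal(one, list(lower = 1, upper = 2))
  same <- weighted_interval(c(3, 3), c(7, 7), c(0.2, 0.8))
  expect_equal(same, list(lower = 3, upper = 7))
  expect_error(weighted_interval(1:2, 2:3, c(1, 0, 0)), "mismatch")
})

test_that("optimization finds the sharp calibrated member", {
  set.seed(402)
  n <- 24L
  y <- rnorm(n, 10, 0.2)
  LA <- y - 0.5; UA <- y + 0.5                   # always covers, width 1
  LB <- y - 50; UB <- y + 50                     # width 100
  w <- optimize_weights(list(L = rbind(A = LA, B = LB),
                             U = rbind(A = UA, B = UB)), y, seed = 2)
  expect_gte(w$weights[["A"]], 0.99)
})

test_that("weights always live on the simplex and respect degeneracy", {
  set.seed(403)
  for (i in 1:10) {
    n <- 12L
    y <- rnorm(n)
    L <- rbind(y - rexp(n), y - rexp(n), y - rexp(n))
    U <- L + matrix(rexp(3 * n), 3)
    w <- optimize_weights(list(L = L, U = U), y, n_restarts = 5L, seed = i)
    expect_equal(sum(w$weights), 1, tolerance = 1e-9)
    expect_true(all(w$weights >= 0))
    expect_lte(w$score, min(w$member_scores) + 1e-6)
  }
  # identical members: any weights give the single-member score
  y <- rnorm(10)
  L <- rbind(y - 1, y - 1); U <- rbind(y + 1, y + 1)
  w <- optimize_weights(list(L = L, U = U), y, n_restarts = 3L)
  expect_equal(w$score, w$member_scores[[1L]], tolerance = 1e-9)
})

test_that("the optimizer matches exhaustive simplex grid search", {
  set.seed(404)
  n <- 24L
  y <- rnorm(n, 5, 2)
  L <- rbind(y - rexp(n, 0.5) - 0.5, 5 - rexp(n, 0.3), y - 4 + rnorm(n))
  U <- L + matrix(rexp(3 * n, 0.25), 3)
  gr <- grid_search_weights(L, U, y, step = 0.01)
  op <- optimize_weights(list(L = L, U = U), y, seed = 3)
  expect_lte(op$score, gr$score + 1e-6)
  expect_lt(gr$score - op$score, 0.05)
})

test_that("combining with one-hot weights reproduces the member", {
  set.seed(405)
  mk <- function() forecast_distribution(matrix(rnorm(200 * 4, 10), 200),
                                         member = "m", scale = "count")
  fcs <- list(a = mk(), b = mk(), c = mk())
  comb <- combine(fcs, c(a = 1, b = 0, c = 0))
  expect_equal(comb$median, summary(fcs$a)$median)
  expect_equal(comb$up95, summary(fcs$a)$up95)
  w <- c(a = 0.3, b = 0.3, c = 0.4)
  cb <- combine(fcs, w)
  bounds <- as.matrix(cb[, c("lo95", "lo80", "median", "up80", "up95")])
  expect_true(all(diff(t(bounds)) >= 0))
  # combined width never exceeds the widest member at each level
  widths <- vapply(fcs, function(f) {
    s <- summary(f); max(s$up95 - s$lo95)
  }, numeric(1))
  expect_lte(max(cb$up95 - cb$lo95), max(widths) + 1e-9)
  expect_error(combine(fcs, c(1, 0)), "mismatch")
})

test_that("weights serialize to JSON", {
  set.seed(406)
  y <- rnorm(10)
  w <- optimize_weights(list(L = rbind(y - 1, y - 2), U = rbind(y + 1, y + 2)),
                        y, n_restarts = 2L)
  path <- withr::local_tempfile(fileext = ".json")
  write_weights(w, path)
  back <- jsonlite::read_json(path)
  expect_equal(sum(unlist(back$weights)), 1, tolerance = 1e-6)
})
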