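make_series <- function(a, k, x_c, cv, seed, design = default_design()) {
  simulate_grain_series(
    element_archetype(if (x_c <= 5) "early" else if (x_c >= 30) "sustained" else "mid",
                      a = a, k = k, x_c = x_c, noise_cv = cv),
    design, seed = seed)
}

test_that("noiseless data recover the generating parameters to 1e-6", {
  s <- make_series(25, 0.25, 13, cv = 0, seed = 1)
  fit <- fit_logistic(s)
  expect_true(fit$converged)
  expect_equal(fit$a, 25, tolerance = 1e-6)
  expect_equal(fit$k, 0.25, tolerance = 1e-6)
  expect_equal(fit$x_c, 13, tolerance = 1e-6)
  # W(x_c) = a / 2 for any converged fit
  expect_equal(predict(fit, fit$x_c), fit$a / 2, tolerance = 1e-12)
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("noiseless recovery holds for all three archetype positions", {
  for (xc in c(2, 13, 33)) {
    s <- make_series(10, 0.3, xc, cv = 0, seed = 2)
    fit <- fit_logistic(s)
    expect_true(fit$converged)
    expect_equal(fit$x_c, xc, tolerance = 1e-4)
    expect_equal(fit$a, 10, tolerance = 1e-3)
  }
})

test_that("fitted SSE never exceeds the exhaustive grid oracle's", {
  s <- make_series(25, 0.25, 13, cv = 0.05, seed = 42)
  fit <- fit_logistic(s)
  sse_fit <- sum((s$observations$value -
                    predict(fit, s$observations$daf))^2)
  sse_grid <- oracle_grid_sse(s$observations$daf, s$observations$value,
                              c(a = 25, k = 0.25, x_c = 13))
  expect_lte(sse_fit, sse_grid + 1e-12)
})

test_that("degenerate inputs are flagged or rejected", {
  d <- default_design()
  const <- grain_series("X", "grain", "mg",
                        expand.grid(daf = d$time_points, replicate = 1:4,
                                    value = 10))
  fit <- fit_logistic(const)
  expect_false(fit$converged)            # k unidentifiable, flagged not thrown
  few <- grain_series("X", "grain", "mg",
                      data.frame(daf = c(5, 9, 13), replicate = 1, value = 1:3))
  expect_error(fit_logistic(few), "input error")
  zero <- grain_series("X", "grain", "mg",
                       expand.grid(daf = d$time_points, replicate = 1:2, value = 0))
  expect_error(fit_logistic(zero), "input error")
})

test_that("rate curve has the closed-form peak and logistic symmetry", {
  s <- make_series(25, 0.25, 13, cv = 0, seed = 1)
  fit <- fit_logistic(s)
  pk <- peak_rate(fit)
  expect_equal(pk$t_peak, 13, tolerance = 1e-6)
  expect_equal(pk$peak_rate, 25 * 0.25 / 4, tolerance = 1e-6)   # a k / 4
  # symmetry about x_c
  rc <- rate_curve(fit, fit$x_c + c(-7, -3, 0, 3, 7))
  expect_equal(rc$rate[1], rc$rate[5], tolerance = 1e-9)
  expect_equal(rc$rate[2], rc$rate[4], tolerance = 1e-9)
  # rate(0) = a k / 4 = 1 for (a = 4, k = 1, x_c = 0)
  expect_identical(logistic_rate(0, 4, 1, 0), 1)
  expect_error(rate_curve(fit_logistic(grain_series("X", "grain", "mg",
    expand.grid(daf = default_design()$time_points, replicate = 1:2, value = 5))),
    1:10), "contract error")
})

test_that("rate integrates to the asymptote (conservation identity)", {
  s <- make_series(25, 0.25, 13, cv = 0, seed = 1)
  fit <- fit_logistic(s)
  half_width <- 40 / fit$k
  int <- integrate(function(x) logistic_rate(x, fit$a, fit$k, fit$x_c),
                   fit$x_c - half_width, fit$x_c + half_width,
                   rel.tol = 1e-10)$value
  expect_equal(int, fit$a, tolerance = 1e-6 * fit$a)
})

test_that("closed-form peak matches a fine-grid argmax within grid spacing", {
  s <- make_series(18, 0.32, 15, cv = 0.05, seed = 5)
  fit <- fit_logistic(s)
  grid <- seq(0, 45, by = 0.001)
  rc <- rate_curve(fit, grid)
  expect_lt(abs(grid[which.max(rc$rate)] - fit$x_c), 0.001 + 1e-9)
  expect_lte(max(rc$rate), rc$peak_rate + 1e-12)
})

test_that("confidence band behaves like a delta-method t band", {
  s0 <- make_series(25, 0.25, 13, cv = 0, seed = 1)
  fit0 <- fit_logistic(s0)
  band0 <- confidence_band(fit0, c(5, 13, 30))
  expect_lt(max(band0$upper - band0$lower), 1e-6)   # zero width without noise

  s <- make_series(25, 0.25, 13, cv = 0.05, seed = 7)
  fit <- fit_logistic(s)
  band <- confidence_band(fit, c(13, 40))
  expect_true(all(band$lower <= band$fit & band$fit <= band$upper))
  width <- band$upper - band$lower
  expect_gt(width[2], width[1])   # wider under extrapolation than at x_c
  expect_error(confidence_band(fit, 1:5, level = 1.2), "parameter error")
})

test_that("95% band has near-nominal pointwise coverage of the true curve", {
  truth <- c(a = 25, k = 0.25, x_c = 13)
  grid <- c(13, 17)
  n_rep <- 500
  hits <- matrix(FALSE, n_rep, length(grid))
  for (i in seq_len(n_rep)) {
    s <- make_series(truth["a"], truth["k"], truth["x_c"], cv = 0.05, seed = 5000 + i)
    fit <- fit_logistic(s)
    if (!fit$converged) next
    b <- confidence_band(fit, grid)
    w_true <- logistic_value(grid, truth["a"], truth["k"], truth["x_c"])
    hits[i, ] <- b$lower <= w_true & w_true <= b$upper
  }
  cov <- colMeans(hits)
  expect_true(all(cov > 0.90 & cov < 0.99))
})

test_that("fitted curve is strictly increasing for k > 0", {
  s <- make_series(25, 0.25, 13, cv = 0.05, seed = 9)
  fit <- fit_logistic(s)
  w <- predict(fit, seq(0, 40, by = 0.5))
  expect_true(all(diff(w) > 0))
})
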