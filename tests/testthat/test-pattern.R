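fit_of <- function(a, k, x_c, cv = 0, seed = 1) {
  label <- if (x_c <= 5) "early" else if (x_c >= 30) "sustained" else "mid"
  fit_logistic(simulate_grain_series(
    element_archetype(label, a = a, k = k, x_c = x_c, noise_cv = cv),
    default_design(), seed = seed))
}

test_that("window rule maps inflection position to pattern class", {
  dm <- fit_of(22, 0.25, 13)
  win <- c(5, 30)
  expect_identical(classify_pattern(fit_of(10, 0.4, 2), dm, win)$pattern, "early")
  expect_identical(classify_pattern(fit_of(10, 0.2, 31), dm, win)$pattern, "sustained")
  lab <- classify_pattern(dm, dm, win)
  expect_identical(lab$pattern, "mid")
  expect_equal(lab$delta_vs_drymatter, 0, tolerance = 1e-9)
  expect_error(classify_pattern(fit_of(10, 0.4, 2), NULL, win), "contract error")
})

test_that("boundary inflections resolve to early / sustained", {
  # construct fits with x_c exactly at the window edges via synthetic objects
  dm <- fit_of(22, 0.25, 13)
  f_lo <- dm; f_lo$x_c <- 5
  f_hi <- dm; f_hi$x_c <- 30
  expect_identical(classify_pattern(f_lo, dm, c(5, 30))$pattern, "early")
  expect_identical(classify_pattern(f_hi, dm, c(5, 30))$pattern, "sustained")
})

test_that("empirical fallback classifies by rate monotonicity", {
  d <- default_design()
  mk <- function(means) {
    grain_series("X", "grain", "mg",
                 data.frame(daf = rep(d$time_points, each = 2),
                            replicate = rep(1:2, 7),
                            value = rep(means, each = 2)))
  }
  # plateau after the first interval (Ca/K-like) -> early
  lab <- classify_empirical(mk(c(2, 10, 10.2, 10.3, 10.3, 10.4, 10.4)), c(5, 30))
  expect_identical(lab$pattern, "early")
  expect_identical(lab$basis, "empirical-fallback")
  # strictly accelerating -> sustained
  expect_identical(
    classify_empirical(mk(c(1, 1.5, 2.5, 4.5, 8, 14, 26)), c(5, 30))$pattern,
    "sustained")
  # hump-shaped rates -> mid
  expect_identical(
    classify_empirical(mk(c(1, 2, 6, 14, 18, 19.5, 20)), c(5, 30))$pattern,
    "mid")
  few <- grain_series("X", "grain", "mg",
                      data.frame(daf = c(5, 9), replicate = 1, value = 1:2))
  expect_error(classify_empirical(few, c(5, 30)), "input error")
})

test_that("fitted and empirical paths agree on noise-free archetypes", {
  d <- default_design()
  dm <- fit_of(22, 0.25, 13)
  # the mid case uses a hump centered in the window so its finite-difference
  # rates are genuinely non-monotone
  cases <- list(c(2, "early"), c(17, "mid"), c(33, "sustained"))
  for (cs in cases) {
    xc <- as.numeric(cs[1])
    label <- if (xc <= 5) "early" else if (xc >= 30) "sustained" else "mid"
    s <- simulate_grain_series(
      element_archetype(label, a = 20, k = 0.3, x_c = xc, noise_cv = 0),
      d, seed = 1)
    fitted <- classify_pattern(fit_logistic(s), dm, c(5, 30))$pattern
    empirical <- classify_empirical(s, c(5, 30))$pattern
    expect_identical(fitted, cs[2])
    expect_identical(empirical, cs[2])
  }
})

test_that("classification is invariant to content-unit rescaling", {
  d <- default_design()
  s <- simulate_grain_series(
    element_archetype("mid", a = 25, k = 0.25, x_c = 13, noise_cv = 0.05),
    d, seed = 4)
  s_scaled <- s
  s_scaled$observations$value <- s$observations$value * 1000
  dm <- fit_of(22, 0.25, 13)
  p1 <- classify_pattern(fit_logistic(s), dm, c(5, 30))
  p2 <- classify_pattern(fit_logistic(s_scaled), dm, c(5, 30))
  expect_identical(p1$pattern, p2$pattern)
  expect_equal(p1$t_peak, p2$t_peak, tolerance = 1e-6)
})

test_that("pattern summaries count a planted 4/9/1 panel correctly", {
  d <- default_design()
  panel <- archetype_panel(4, 9, 1, d, seed = 21, noise_cv = 0)
  dm <- fit_of(22, 0.25, 13)
  labels <- do.call(rbind, lapply(names(panel), function(el) {
    s <- simulate_grain_series(panel[[el]], d, seed = 100, element = el)
    classify_element(s, fit_logistic(s), dm, c(5, 30))
  }))
  sm <- summarize_patterns(labels)
  expect_identical(sm$n, c(4L, 9L, 1L))
  expect_identical(sum(sm$n), nrow(labels))
  one <- summarize_patterns(labels[1, , drop = FALSE])
  expect_identical(sum(one$n), 1L)
  expect_error(summarize_patterns(labels[0, ]), "input error")
})
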