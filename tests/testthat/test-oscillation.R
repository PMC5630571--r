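test_that("identical sinusoids give exact period, zero lag, synchrony one", {
  t <- seq(0, 12, by = 0.05)
  s <- 3 + sin(2 * pi * t / 2)
  r <- detect_oscillations(t, s, s)
  expect_true(r$oscillating)
  expect_equal(r$h2$period_h, 2, tolerance = 0.05 + 1e-9)
  expect_equal(r$co2$period_h, 2, tolerance = 0.05 + 1e-9)
  expect_equal(r$lag_h, 0)
  expect_equal(r$synchrony, 1, tolerance = 1e-9)
  expect_true(r$in_phase)
  # Amplitude recovered after period-matched detrending.
  expect_equal(r$h2$amplitude_pct, 1, tolerance = 0.05)
})

test_that("synchrony of a series with its negation is minus one", {
  t <- seq(0, 12, by = 0.05)
  s <- sin(2 * pi * t / 2)
  r <- detect_oscillations(t, 3 + s, 3 - s)
  expect_equal(r$synchrony, -1, tolerance = 1e-9)
  expect_false(r$in_phase)
})

test_that("flat, monotone and pure-noise series report no oscillation", {
  t <- seq(0, 12, by = 0.05)
  expect_false(detect_oscillations(t, rep(3, length(t)),
                                   rep(3, length(t)))$oscillating)
  expect_false(detect_oscillations(t, 3 + 0.1 * t, 3 + 0.1 * t)$oscillating)
  set.seed(5)
  expect_false(detect_oscillations(t, rnorm(length(t), 3, 0.02),
                                   rnorm(length(t), 3, 0.02))$oscillating)
})

test_that("a quarter-period offset is recovered as the cross-correlation lag", {
  t <- seq(0, 12, by = 0.05)
  a <- 3 + sin(2 * pi * t / 2)
  b <- 3 + sin(2 * pi * (t - 0.5) / 2)
  r <- detect_oscillations(t, a, b)
  expect_equal(abs(r$lag_h), 0.5, tolerance = 0.05 + 1e-9)
  expect_false(r$in_phase)
})

test_that("period estimation degrades monotonically-bounded with noise", {
  t <- seq(0, 24, by = 0.05)
  clean <- 3 + 0.5 * sin(2 * pi * t / 2)
  err <- vapply(c(0, 0.05, 0.15), function(sd) {
    set.seed(99)
    r <- detect_oscillations(t, clean + rnorm(length(t), 0, sd),
                             clean + rnorm(length(t), 0, sd))
    abs(r$h2$period_h - 2)
  }, numeric(1))
  expect_lt(err[1], 0.051)
  expect_lt(err[3], 0.3)  # still close under strong noise
})

test_that("uniform sampling is required", {
  expect_error(detect_oscillations(c(0, 1, 3), 1:3, 1:3), "uniformly")
})

test_that("onset detection interpolates the first crossing", {
  t <- seq(0, 6, by = 1)
  ramp <- t  # 0 -> 6 %v/v over 6 h
  expect_equal(onset_detection(t, ramp, 3), 3)
  expect_equal(onset_detection(t, ramp, 2.5), 2.5)
  expect_equal(onset_detection(t, ramp, 0), 0)  # at-threshold start
  expect_error(onset_detection(t, ramp + 5, 3), "starts above")
  below <- onset_detection(t, ramp / 10, 3)
  expect_true(is.na(below))
  expect_match(attr(below, "diagnostic"), "never")
})

test_that("growth-rate break separates piecewise exponential growth", {
  t <- seq(0, 10, by = 0.25)
  # Single exponential: equal slopes, no significant break.
  x1 <- 0.1 * exp(0.3 * t)
  b1 <- growth_rate_break(t, x1)
  expect_equal(b1$mu_before, 0.3, tolerance = 1e-6)
  expect_equal(b1$mu_after, 0.3, tolerance = 1e-6)
  expect_false(b1$significant)
  # Piecewise 0.3 then 0.1 with break at t = 5.
  x2 <- ifelse(t <= 5, 0.1 * exp(0.3 * t), 0.1 * exp(0.3 * 5) *
                 exp(0.1 * (t - 5)))
  b2 <- growth_rate_break(t, x2)
  expect_equal(b2$break_time_h, 5, tolerance = 0.25 + 1e-9)
  expect_equal(b2$mu_before, 0.3, tolerance = 0.02)
  expect_equal(b2$mu_after, 0.1, tolerance = 0.02)
  expect_true(b2$significant)
  # Constant biomass: zero slopes.
  b3 <- growth_rate_break(t, rep(1, length(t)))
  expect_equal(b3$mu_before, 0)
  expect_equal(b3$mu_after, 0)
  expect_false(b3$significant)
  expect_error(growth_rate_break(1:5, exp(1:5)), ">= 6 points")
  expect_error(growth_rate_break(t, x1 - 1), "positive")
})
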