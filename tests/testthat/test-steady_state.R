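D <- 0.135

test_that("a constant series yields a window starting at three residence times", {
  t <- seq(0, 60, by = 0.5)
  s <- data.frame(time_h = t, x = rep(2, length(t)))
  w <- detect_steady_state(s, D)
  expect_true(is_steady_window(w))
  expect_equal(w$start, 3 / D)
  expect_equal(w$end, 60)
  expect_gte(w$residence_times_elapsed, 3)
})

test_that("persistent drift beyond tolerance is rejected with a diagnostic", {
  t <- seq(0, 60, by = 0.5)
  # 5% of the mean per residence time drift, tolerance 1%.
  s <- data.frame(time_h = t, x = 2 * (1 + 0.05 * D * t))
  w <- detect_steady_state(s, D, rel_tol = 0.01)
  expect_false(is_steady_window(w))
  expect_match(attr(w, "diagnostic"), "x")
})

test_that("an exponential settle is accepted once the residual is inside tolerance", {
  t <- seq(0, 120, by = 0.5)
  s <- data.frame(time_h = t, x = 5 * (1 - exp(-D * t)))
  rel_tol <- 0.01
  w <- detect_steady_state(s, D, rel_tol = rel_tol)
  expect_true(is_steady_window(w))
  # Independent check with lm: the accepted window satisfies the trend
  # criterion, and the plateau is recovered.
  keep <- t >= w$start
  slope <- unname(coef(lm(s$x[keep] ~ t[keep]))[2])
  expect_lt(abs(slope) * (max(t) - w$start), rel_tol * mean(s$x[keep]))
  expect_equal(mean(s$x[keep]), 5, tolerance = 0.02)
  # A far tighter tolerance forces a later start (or no window at all).
  w_tight <- detect_steady_state(s, D, rel_tol = 1e-6)
  expect_true(!is_steady_window(w_tight) || w_tight$start > w$start)
})

test_that("windows never begin before three residence times after a perturbation", {
  t <- seq(0, 120, by = 0.5)
  s <- data.frame(time_h = t, x = rep(1, length(t)))
  w <- detect_steady_state(s, D, perturbations = c(10, 40))
  expect_true(is_steady_window(w))
  expect_gte(w$start, 40 + 3 / D)
})

test_that("a series shorter than the residence-time rule is rejected", {
  t <- seq(0, 10, by = 0.5)
  s <- data.frame(time_h = t, x = rep(1, length(t)))
  w <- detect_steady_state(s, D)
  expect_false(is_steady_window(w))
  expect_match(attr(w, "diagnostic"), "residence")
})

test_that("summaries are exact for constants and partition-invariant", {
  t <- seq(0, 60, by = 0.5)
  s <- data.frame(time_h = t, x = rep(3.5, length(t)))
  w <- detect_steady_state(s, D)
  rec <- summarize_steady_state(s, w)
  expect_equal(ss_mean(rec, "x"), 3.5)
  expect_equal(rec$se[rec$variable == "x"], 0)
  # Two half-windows agree with the whole window on a constant signal.
  mid <- (w$start + w$end) / 2
  w1 <- structure(list(start = w$start, end = mid), class = "steady_window")
  w2 <- structure(list(start = mid, end = w$end), class = "steady_window")
  expect_equal(ss_mean(summarize_steady_state(s, w1), "x"),
               ss_mean(summarize_steady_state(s, w2), "x"))
})

test_that("summary of iid noise is within 3 SE of the true level", {
  t <- seq(0, 60, by = 0.25)
  set.seed(11)
  s <- data.frame(time_h = t, x = 3 + rnorm(length(t), 0, 0.1))
  w <- detect_steady_state(s, D)
  rec <- summarize_steady_state(s, w)
  expect_lt(abs(ss_mean(rec, "x") - 3), 3 * rec$se[rec$variable == "x"])
})

test_that("summaries require at least three samples", {
  s <- data.frame(time_h = c(0, 50, 100), x = 1)
  w <- structure(list(start = 40, end = 110), class = "steady_window")
  expect_error(summarize_steady_state(s, w), ">= 3 samples")
})
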