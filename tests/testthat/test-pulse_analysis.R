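make_response <- function(dose, h2 = 2.5, co = 1, bio = 0.02) {
  structure(list(dose_mmol = dose, extra_h2_mol = h2 * dose / 1000,
                 displaced_co_mol = co * dose / 1000,
                 biomass_increase_g = bio * dose, washout = FALSE),
            class = "pulse_response")
}

test_that("dose-response slopes are exact on noise-free pairs", {
  res <- lapply(c(2.17, 4.34, 8.68), make_response)
  fit <- stoichiometry_slopes(res)
  expect_equal(fit$slope[fit$response == "h2_per_no2"], 2.5,
               tolerance = 1e-9)
  expect_equal(fit$slope[fit$response == "co_per_no2"], 1, tolerance = 1e-9)
  expect_equal(fit$slope[fit$response == "biomass_per_no2"], 0.02,
               tolerance = 1e-9)
  expect_equal(fit$intercept, rep(0, 3), tolerance = 1e-12)
})

test_that("a single dose in forced-origin mode gives slope r/d", {
  res <- list(make_response(5))
  fit <- stoichiometry_slopes(res, intercept = FALSE)
  expect_equal(fit$slope[fit$response == "h2_per_no2"], 2.5,
               tolerance = 1e-9)
  expect_error(stoichiometry_slopes(res), "at least 2")
})

test_that("a singular design (all doses equal) is rejected", {
  res <- lapply(c(5, 5, 5), make_response)
  expect_error(stoichiometry_slopes(res), "singular")
})

test_that("washout doses are excluded from regression and reported", {
  res <- c(lapply(c(2.17, 4.34, 8.68), make_response),
           list(structure(list(dose_mmol = 21, washout = TRUE),
                          class = "pulse_response")))
  fit <- stoichiometry_slopes(res)
  expect_equal(attr(fit, "washout_doses_mmol"), 21)
  expect_equal(fit$slope[fit$response == "co_per_no2"], 1, tolerance = 1e-9)
})

# Shared fixture for direct response quantification: a constant-uptake run
# with a rectangular deviation of known area.
rect_uptake_fixture <- function(depth_co = 0.004, extra_h2 = 0.01,
                                from = 32, to = 34) {
  t <- seq(0, 60, by = 0.1)
  up <- data.frame(time_h = t, o2 = 0, n2 = 0, ar = 0,
                   co = 0.009, co2 = 0, h2 = 0.02)
  sel <- t > from & t <= to
  up$co[sel] <- up$co[sel] - depth_co
  up$h2[sel] <- up$h2[sel] + extra_h2
  pre <- up[t < 30, ]
  pre$biomass_g_l <- 4
  w <- detect_steady_state(pre, 0.135)
  baseline <- summarize_steady_state(pre, w)
  biomass <- data.frame(time_h = t, biomass_g_l = 4)
  list(uptake = up, baseline = baseline, biomass = biomass)
}

test_that("no deviation from baseline gives zero responses", {
  fx <- rect_uptake_fixture(depth_co = 0, extra_h2 = 0)
  ev <- pulse_event(30, 3.1)
  r <- quantify_pulse_response(fx$uptake, fx$biomass, ev, fx$baseline, 0.135)
  expect_equal(r$displaced_co_mol, 0, tolerance = 1e-12)
  expect_equal(r$extra_h2_mol, 0, tolerance = 1e-12)
  expect_equal(r$biomass_increase_g, 0, tolerance = 1e-12)
})

test_that("a rectangular deviation integrates to its analytic area", {
  fx <- rect_uptake_fixture(depth_co = 0.004, extra_h2 = 0.01,
                            from = 32, to = 34)
  ev <- pulse_event(30, 3.1)
  r <- quantify_pulse_response(fx$uptake, fx$biomass, ev, fx$baseline, 0.135)
  grid_err <- 0.1 * 0.004  # one sample at each edge of the rectangle
  expect_equal(r$displaced_co_mol, 0.004 * 2, tolerance = 2 * grid_err)
  expect_equal(r$extra_h2_mol, 0.01 * 2, tolerance = 2 * 0.1 * 0.01)
  expect_false(r$partial)
})

test_that("response quantification is linear in the deviation", {
  fx1 <- rect_uptake_fixture(depth_co = 0.002, extra_h2 = 0.005)
  fx2 <- rect_uptake_fixture(depth_co = 0.004, extra_h2 = 0.01)
  ev <- pulse_event(30, 3.1)
  r1 <- quantify_pulse_response(fx1$uptake, fx1$biomass, ev, fx1$baseline,
                                0.135)
  r2 <- quantify_pulse_response(fx2$uptake, fx2$biomass, ev, fx2$baseline,
                                0.135)
  expect_equal(r2$displaced_co_mol, 2 * r1$displaced_co_mol,
               tolerance = 1e-9)
  expect_equal(r2$extra_h2_mol, 2 * r1$extra_h2_mol, tolerance = 1e-9)
})

test_that("a transient that never returns is flagged partial", {
  fx <- rect_uptake_fixture(depth_co = 0.004, extra_h2 = 0,
                            from = 32, to = 60)
  ev <- pulse_event(30, 3.1)
  r <- quantify_pulse_response(fx$uptake, fx$biomass, ev, fx$baseline, 0.135)
  expect_true(r$partial)
  # Integration capped at one residence time.
  expect_equal(diff(r$window_h), 1 / 0.135, tolerance = 1e-9)
})

test_that("doses above the washout threshold are flagged, not analyzed", {
  ev <- pulse_event(30, 30)
  expect_true(ev$washout)
  fx <- rect_uptake_fixture()
  r <- quantify_pulse_response(fx$uptake, fx$biomass, ev, fx$baseline, 0.135)
  expect_true(r$washout)
  expect_null(r$displaced_co_mol)
})
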