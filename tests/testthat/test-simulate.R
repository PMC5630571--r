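test_that("heterotrophic generator output closes carbon and electron balances", {
  sim <- simulate_chemostat(scenario_heterotrophic())
  gap <- conservation_gap(sim)
  expect_lt(gap[["carbon"]], 1e-9)
  expect_lt(gap[["electron"]], 1e-9)
  expect_equal(sim$truth$expected_carbon_recovery, 1)
  expect_equal(sim$truth$expected_electron_recovery, 1)
})

test_that("low-syngas CO oxidation trades CO for CO2 + H2 mol for mol", {
  sim <- simulate_chemostat(scenario_low_syngas(start_at_steady = TRUE))
  expect_equal(sim$truth$regime, "co_oxidation")
  x <- sim$truth$co_oxidation_mol_h
  expect_gt(x, 0)
  last <- nrow(sim$flows)
  co_consumed <- sim$inlet$co - sim$flows$co[last]
  extra_co2 <- sim$flows$co2[last] - sim$inlet$co2 - sim$truth$e_co2_mol_h
  extra_h2 <- sim$flows$h2[last] - sim$inlet$h2 - sim$truth$e_h2_mol_h
  expect_equal(co_consumed, x, tolerance = 1e-12)
  expect_equal(extra_co2, x, tolerance = 1e-12)
  expect_equal(extra_h2, x, tolerance = 1e-12)
})

test_that("the regime switch follows the sparged CO2 fraction", {
  expect_equal(simulate_chemostat(scenario_low_syngas())$truth$regime,
               "co_oxidation")
  expect_equal(simulate_chemostat(scenario_high_syngas())$truth$regime,
               "c1_assimilation")
  # C-1 assimilation demanded in the oxidation regime is rejected.
  expect_error(simulate_chemostat(sim_scenario(syngas_fraction = 9,
                                               c1_fraction = 0.1)),
               "regime")
  expect_error(simulate_chemostat(sim_scenario(c1_fraction = 0.1)), "regime")
})

test_that("configured C-1 assimilation does not raise biomass", {
  het <- simulate_chemostat(scenario_heterotrophic())
  hi <- simulate_chemostat(scenario_high_syngas())
  expect_equal(max(hi$liquid$biomass_g_l), max(het$liquid$biomass_g_l),
               tolerance = 1e-12)
  # ...but raises butanol and butyrate product flux.
  expect_gt(max(hi$liquid$butanol_g_l), max(het$liquid$butanol_g_l))
})

test_that("infeasible scenarios are rejected with conservation errors", {
  expect_error(simulate_chemostat(sim_scenario(
    base_yields = c(butanol = 0.8, butyrate = 0.2, acetate = 0.05,
                    acetone = 0, ethanol = 0))),
    "conservation violation")
  expect_error(simulate_chemostat(sim_scenario(
    syngas_fraction = 60, c1_fraction = 0.6)), "conservation violation")
  expect_error(simulate_chemostat(sim_scenario(solvent_shift_h2 = 0.2)),
               "butyrate")
})

test_that("same seed reproduces the noisy output bit for bit", {
  sc <- scenario_high_syngas(noise_gas_pct = 0.05, noise_liquid_g_l = 0.05,
                             noise_biomass_g_l = 0.02, seed = 77)
  a <- simulate_chemostat(sc)
  b <- simulate_chemostat(sc)
  expect_identical(a$gas, b$gas)
  expect_identical(a$liquid, b$liquid)
  c <- simulate_chemostat(scenario_high_syngas(noise_gas_pct = 0.05,
                                               seed = 78))
  expect_false(identical(a$gas, c$gas))
})

test_that("noise injection matches the configured SD and zero SD is identity", {
  sc0 <- scenario_heterotrophic(duration_h = 250, dt_h = 0.25)
  sim0 <- simulate_chemostat(sc0)
  noisy <- add_measurement_noise(sim0, noise_gas_pct = 0.2, seed = 3)
  resid <- noisy$gas$co2_pct - sim0$gas$co2_pct
  resid <- resid[sim0$gas$co2_pct > 1]  # away from the truncation bound
  expect_gt(length(resid), 900)
  expect_equal(stats::sd(resid), 0.2, tolerance = 0.15 * 0.2)
  expect_identical(add_measurement_noise(sim0), sim0)
})

test_that("fed-batch truth round-trips through the oscillation module", {
  fb <- simulate_fedbatch(sim_scenario(mode = "fedbatch",
                                       osc_amplitude_pct = 0.5,
                                       fb_duration_h = 45))
  r <- detect_oscillations(fb$gas$time_h, fb$gas$h2_pct, fb$gas$co2_pct)
  expect_true(r$oscillating)
  expect_equal(r$h2$period_h, fb$truth$period_h, tolerance = 0.02 + 1e-9)
  expect_equal(r$co2$period_h, fb$truth$period_h, tolerance = 0.02 + 1e-9)
  expect_equal(r$h2$amplitude_pct, 0.5, tolerance = 0.05)
  expect_true(r$in_phase)
  onset <- onset_detection(fb$gas$time_h, fb$gas$h2_pct,
                           fb$scenario$onset_pct)
  expect_equal(onset, fb$truth$onset_h, tolerance = fb$scenario$fb_dt_h)
})

test_that("the diauxic break is recovered before the biomass cap binds", {
  fb <- simulate_fedbatch(sim_scenario(mode = "fedbatch"))
  i <- seq(1, nrow(fb$liquid), by = 25)
  br <- growth_rate_break(fb$liquid$time_h[i], fb$liquid$biomass_g_l[i])
  expect_equal(br$break_time_h, fb$truth$break_h, tolerance = 0.5)
  expect_equal(br$mu_before, fb$truth$mu1, tolerance = 0.02)
  expect_equal(br$mu_after, fb$truth$mu2, tolerance = 0.02)
  expect_true(br$significant)
})

test_that("zero oscillation amplitude gives a monotone ramp and no detection", {
  fb <- simulate_fedbatch(sim_scenario(mode = "fedbatch",
                                       osc_amplitude_pct = 0))
  r <- detect_oscillations(fb$gas$time_h, fb$gas$h2_pct, fb$gas$co2_pct)
  expect_false(r$oscillating)
})

test_that("nitrite pulses round-trip the configured stoichiometries", {
  sc <- scenario_high_syngas(duration_h = 70, start_at_steady = TRUE)
  sim <- simulate_chemostat(sc)
  sched <- data.frame(time_h = c(30, 45, 60), conc_mM = c(3.1, 6.2, 12.4))
  psim <- inject_nitrite_pulses(sim, sched)
  fit <- analyze_pulses(psim)$slopes
  expect_equal(fit$slope[fit$response == "h2_per_no2"], 2.5,
               tolerance = 0.02 * 2.5)
  expect_equal(fit$slope[fit$response == "co_per_no2"], 1, tolerance = 0.02)
  expect_equal(fit$slope[fit$response == "biomass_per_no2"], 0.02,
               tolerance = 0.02 * 0.02)
})

test_that("a dose above the washout threshold decays biomass at rate D", {
  sc <- scenario_high_syngas(duration_h = 70, start_at_steady = TRUE)
  sim <- simulate_chemostat(sc)
  psim <- inject_nitrite_pulses(sim, data.frame(time_h = 30, conc_mM = 30))
  ev <- psim$truth$pulses$events[[1]]
  expect_true(ev$washout)
  t <- psim$liquid$time_h
  x0 <- psim$liquid$biomass_g_l[t == 30]
  x10 <- psim$liquid$biomass_g_l[t == 40]
  expect_equal(log(x0 / x10) / 10, sc$dilution_rate, tolerance = 1e-9)
})

test_that("pulse schedules violating spacing or settling are rejected", {
  sc <- scenario_high_syngas(duration_h = 70, start_at_steady = TRUE)
  sim <- simulate_chemostat(sc)
  expect_error(inject_nitrite_pulses(sim, data.frame(time_h = 10,
                                                     conc_mM = 3.1)),
               "steady state")
  expect_error(inject_nitrite_pulses(
    sim, data.frame(time_h = c(30, 33), conc_mM = c(3.1, 6.2))),
    "overlap")
})

test_that("carbon and electron conservation holds across random scenarios", {
  for (seed in 1:25) {
    sim <- random_scenario(seed)
    gap <- conservation_gap(sim)
    expect_lt(gap[["carbon"]], 1e-9)
    expect_lt(gap[["electron"]], 1e-9)
  }
})
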