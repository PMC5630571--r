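test_that("Henry's law uses the tabulated constants", {
  expect_equal(henry_concentration("co", 1), 0.0225)
  expect_equal(henry_concentration("co2", 0), 0)
  expect_equal(henry_concentration("h2", 0.5), 0.0007)
  expect_error(henry_concentration("n2", 1), "constant provided in source")
  expect_error(henry_concentration("ar", 1), "constant provided in source")
})

test_that("fraction to molar flow is the ideal-gas conversion at 37 C", {
  expect_equal(fraction_to_molar_flow(100, 12.48),
               12.48 / (0.082057 * 310.15), tolerance = 1e-12)
  expect_equal(fraction_to_molar_flow(100, 12.48), 0.4904, tolerance = 1e-4)
  expect_equal(fraction_to_molar_flow(0, 5), 0)
  expect_equal(fraction_to_molar_flow(50, 12.48),
               fraction_to_molar_flow(100, 12.48) / 2)
})

test_that("net gas consumption follows I + E - O and its zero cases", {
  expect_equal(net_gas_consumption(output = 1, input = 1), 0)
  expect_equal(net_gas_consumption(output = 1.2, input = 0, endogenous = 1.2),
               0)
  expect_equal(net_gas_consumption(output = 0.9, input = 1, endogenous = 0.2),
               0.3)
  # Antisymmetry: production and consumption of equal magnitude mirror.
  d <- 0.17
  expect_equal(net_gas_consumption(1 - d, 1, 0),
               -net_gas_consumption(1 + d, 1, 0))
  expect_error(net_gas_consumption(-0.1, 1, 0))
})

test_that("gas series validation catches bad fractions and time", {
  fr <- data.frame(o2_pct = 0, n2_pct = 97, co_pct = 0, co2_pct = 3,
                   h2_pct = 0, ar_pct = 0)
  expect_s3_class(gas_series(0:3, fr[rep(1, 4), ], 12.48), "gas_series")
  bad <- fr; bad$co2_pct <- 120; bad$n2_pct <- -20
  expect_error(gas_series(0:3, bad[rep(1, 4), ], 12.48), "outside")
  low <- fr; low$n2_pct <- 60
  expect_error(gas_series(0:3, low[rep(1, 4), ], 12.48), "sum")
  expect_error(gas_series(c(0, 1, 1, 2), fr[rep(1, 4), ], 12.48),
               "strictly increasing")
})

test_that("endogenous baseline recovers a constant production rate", {
  s <- flat_gas_series(c(co2 = 3))
  b <- endogenous_baseline(s, dilution_rate = 0.135)
  expect_equal(b$rate_mol_h[b$gas == "co2"],
               fraction_to_molar_flow(3, 12.48), tolerance = 1e-9)
  expect_equal(b$rate_mol_h[b$gas == "co"], 0, tolerance = 1e-12)
  # Zero-emission control: all baselines zero.
  s0 <- flat_gas_series(c(n2 = 100))
  b0 <- endogenous_baseline(s0, dilution_rate = 0.135)
  expect_true(all(abs(b0$rate_mol_h) < 1e-12))
})

test_that("baseline mean of a noisy constant signal is within 3 SE", {
  s <- flat_gas_series(c(co2 = 3), hours = 60, dt = 0.25)
  set.seed(42)
  s$co2_pct <- pmax(0, s$co2_pct + rnorm(nrow(s), 0, 0.05))
  s$n2_pct <- 100 - s$co2_pct
  b <- endogenous_baseline(s, dilution_rate = 0.135)
  i <- which(b$gas == "co2")
  truth <- fraction_to_molar_flow(3, 12.48)
  expect_lt(abs(b$rate_mol_h[i] - truth), 3 * b$se[i])
  expect_gt(b$se[i], 0)
})

test_that("zero biological exchange gives zero net consumption for every gas", {
  sim <- simulate_chemostat(sim_scenario(
    syngas_fraction = 60, c1_fraction = 0,
    base_yields = c(butanol = 0, butyrate = 0, acetate = 0, acetone = 0,
                    ethanol = 0),
    biomass_yield = 0, sugar_consumed_fraction = 0))
  inlet <- sim$inlet
  last <- nrow(sim$flows)
  for (g in c("co", "co2", "h2", "n2")) {
    expect_equal(net_gas_consumption(sim$flows[[g]][last], inlet[[g]]), 0,
                 tolerance = 1e-9)
  }
})

test_that("dissolved inventory stays below the gas fed per residence time", {
  frac <- c(co = 12, co2 = 19, h2 = 3)
  inv <- dissolved_inventory(frac, volume_l = 0.7)
  fed_per_tau <- function(g) {
    fraction_to_molar_flow(frac[[g]], 12.48) / 0.135  # mol per residence time
  }
  mm <- c(co = 28.01, co2 = 44.01, h2 = 2.016)
  for (g in c("co", "h2")) {
    expect_lt(inv$inventory_g[inv$gas == g], fed_per_tau(g) * mm[[g]])
  }
})
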