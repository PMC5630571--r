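# Synthetic fermentation-data generator.
#
# Chemostat steady states are generated algebraically from configured fluxes
# (the analysis consumes steady states and transients, not kinetic
# mechanisms): a base sugar fermentation whose CO2 and H2 yields are solved
# to close the carbon and electron balances exactly, plus the carbon-electron
# flow logic of mixotrophic capture — CO oxidation (CO + H2O -> CO2 + H2,
# 1:1:1) when the sparged CO2 fraction is below the switch threshold, C-1
# assimilation into acetyl-CoA-derived products (butanol/butyrate, without
# biomass gain) when above. Every configured flux is stored in a truth record
# so analysis modules can be round-trip tested; conservation is asserted to
# 1e-9 before noise.

#' Build a simulation scenario
#'
#' Defaults are the reference cultivation conditions: chemostat at
#' D = 0.135 1/h, 0.7 L, sparged at 12.48 L/h with a syngas blend
#' (100% syngas = 20% CO / 20% CO2 / 10% H2 / 50% N2) balanced with nitrogen,
#' fed 30 g/L sucrose + 15 g/L fructose.
#'
#' @param mode `"chemostat"` or `"fedbatch"`.
#' @param dilution_rate D, 1/h.
#' @param volume_l Culture volume, L.
#' @param sparge_flow_l_h Total sparge flow, L/h.
#' @param temperature_c,pressure_atm Reference gas conditions.
#' @param syngas_fraction %v/v of the syngas blend in the sparge (0 = pure
#'   N2, heterotrophic control).
#' @param blend Named blend composition of 100% syngas (%v/v, sums to 100).
#' @param sugar_feed Named feed concentrations, g/L.
#' @param sugar_consumed_fraction Fraction of fed sugar consumed at steady
#'   state.
#' @param base_yields Named heterotrophic product yields, C-mol/C-mol sugar.
#' @param biomass_yield Yx, C-mol/C-mol.
#' @param c1_fraction C-1 assimilation flux as a fraction of sugar carbon
#'   (C-mol/C-mol); requires the assimilation regime.
#' @param c1_butanol_share Share of C-1 carbon routed to butanol (rest to
#'   butyrate).
#' @param c1_co_share Share of C-1 carbon drawn from CO (rest from CO2).
#' @param h2_uptake_max_fraction Cap on external H2 uptake as a fraction of
#'   inlet H2; remaining electron demand is covered by suppressing endogenous
#'   H2 evolution (reduced ferredoxin diverted to carbon fixation).
#' @param solvent_shift_h2 Electron-sink solventogenic shift: mol H2 per
#'   C-mol sugar redirected from endogenous evolution into converting
#'   butyrate to butanol (2 C-mol butyrate per mol H2).
#' @param co2_switch_threshold Sparged (inlet) CO2 fraction, %v/v, separating
#'   the CO-oxidation regime (below) from C-1 assimilation (above).
#' @param co_ox_fraction Fraction of inlet CO oxidized in the oxidation
#'   regime.
#' @param h2_per_no2,co_per_no2 Nitrite-pulse stoichiometries, mol gas per
#'   mol NO2.
#' @param biomass_per_no2 Biomass gain per nitrite dose, g/mmol.
#' @param washout_mM Nitrite concentration above which washout occurs.
#' @param pulse_tau_h Transient time constant of a nitrite pulse, h.
#' @param osc_period_h,osc_amplitude_pct Fed-batch oscillation parameters.
#' @param onset_pct Gas fraction at which the oscillation activates, %v/v.
#' @param fb_duration_h,fb_dt_h,fb_x0,fb_xmax,fb_mu1,fb_mu2,fb_break_h,fb_gas_per_x
#'   Fed-batch growth and gas-ramp parameters: piecewise specific growth rate
#'   `fb_mu1`/`fb_mu2` (1/h) breaking at `fb_break_h`, biomass cap
#'   `fb_xmax` (g/L), and gas emission `fb_gas_per_x` (%v/v per g/L biomass).
#' @param start_at_steady Begin the chemostat series at the settled steady
#'   state instead of the exponential approach to it (used for pulse studies,
#'   where steady state is re-established before dosing).
#' @param duration_h,dt_h Chemostat series length and sampling step, h.
#' @param noise_gas_pct,noise_liquid_g_l,noise_biomass_g_l Gaussian
#'   measurement noise SDs per instrument channel (0 = noise-free).
#' @param seed RNG seed making every output bit-reproducible.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(mode = c("chemostat", "fedbatch"),
                         dilution_rate = 0.135, volume_l = 0.7,
                         sparge_flow_l_h = 12.48,
                         temperature_c = 37, pressure_atm = 1,
                         syngas_fraction = 0,
                         blend = c(co = 20, co2 = 20, h2 = 10, n2 = 50),
                         sugar_feed = c(sucrose = 30, fructose = 15),
                         sugar_consumed_fraction = 0.9,
                         base_yields = c(butanol = 0.25, butyrate = 0.14,
                                         acetate = 0.05, acetone = 0.04,
                                         ethanol = 0.03),
                         biomass_yield = 0.12,
                         c1_fraction = 0, c1_butanol_share = 0.75,
                         c1_co_share = 0.4, h2_uptake_max_fraction = 0.7,
                         solvent_shift_h2 = 0,
                         co2_switch_threshold = 5, co_ox_fraction = 0.6,
                         h2_per_no2 = 2.5, co_per_no2 = 1,
                         biomass_per_no2 = 0.02, washout_mM = 24,
                         pulse_tau_h = 1,
                         osc_period_h = 2, osc_amplitude_pct = 0.5,
                         onset_pct = 3,
                         fb_duration_h = 30, fb_dt_h = 0.02, fb_x0 = 0.05,
                         fb_xmax = 8, fb_mu1 = 0.3, fb_mu2 = 0.1,
                         fb_break_h = 10, fb_gas_per_x = 0.75,
                         start_at_steady = FALSE,
                         duration_h = 60, dt_h = 0.25,
                         noise_gas_pct = 0, noise_liquid_g_l = 0,
                         noise_biomass_g_l = 0, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(dilution_rate > 0, volume_l > 0, sparge_flow_l_h > 0,
            syngas_fraction >= 0, syngas_fraction <= 100,
            abs(sum(blend) - 100) < 1e-9,
            all(base_yields >= 0), biomass_yield >= 0,
            c1_fraction >= 0, c1_butanol_share >= 0, c1_butanol_share <= 1,
            c1_co_share >= 0, c1_co_share <= 1,
            solvent_shift_h2 >= 0, co_ox_fraction >= 0, co_ox_fraction <= 1,
            noise_gas_pct >= 0, noise_liquid_g_l >= 0, noise_biomass_g_l >= 0)
  structure(as.list(environment()), class = "sim_scenario")
}

#' Heterotrophic (N2-sparged) control scenario
#' @param ... Overrides passed to [sim_scenario()].
#' @export
scenario_heterotrophic <- function(...) {
  sim_scenario(syngas_fraction = 0, ...)
}

#' Low-syngas scenario (CO-oxidation regime)
#'
#' 9% syngas: sparged CO2 is 1.8 %v/v, below the 5% switch, so CO is oxidized
#' to CO2 + H2 and no carbon is assimilated.
#' @param ... Overrides passed to [sim_scenario()].
#' @export
scenario_low_syngas <- function(...) {
  sim_scenario(syngas_fraction = 9, ...)
}

#' Medium-syngas scenario (C-1 assimilation regime)
#'
#' 32% syngas with C-1 assimilation of 11% of sugar carbon and a solventogenic
#' shift sized to the reported medium-syngas condition (19% combined
#' carbon-electron excess).
#' @param ... Overrides passed to [sim_scenario()].
#' @export
scenario_medium_syngas <- function(...) {
  sim_scenario(syngas_fraction = 32, c1_fraction = 0.11,
               solvent_shift_h2 = 0.06375, ...)
}

#' High-syngas scenario (C-1 assimilation regime)
#'
#' 60% syngas with C-1 assimilation of 17% of sugar carbon and a solventogenic
#' shift sized to the reported high-syngas condition (27% combined
#' carbon-electron excess).
#' @param ... Overrides passed to [sim_scenario()].
#' @export
scenario_high_syngas <- function(...) {
  sim_scenario(syngas_fraction = 60, c1_fraction = 0.17,
               solvent_shift_h2 = 0.05125, ...)
}

# Sugar feed in C-mol/L and the consumed carbon flux.
sugar_carbon <- function(scenario, registry) {
  feed_cmol <- vapply(names(scenario$sugar_feed), function(s) {
    cmp <- registry[[s]]
    scenario$sugar_feed[[s]] / cmp$molar_mass * cmp$atoms[["C"]]
  }, numeric(1))
  consumed_cmol <- feed_cmol * scenario$sugar_consumed_fraction
  list(feed_cmol_l = feed_cmol,
       consumed_cmol_l = consumed_cmol,
       flux_cmol_h = sum(consumed_cmol) * scenario$dilution_rate *
         scenario$volume_l)
}

#' Simulate a chemostat steady state
#'
#' Solves the configured carbon-electron flow algebraically (base
#' fermentation closed on carbon and electrons, optional solventogenic shift,
#' CO oxidation or C-1 assimilation by the inlet-CO2 regime switch), builds
#' gas and liquid time series that settle exponentially to the steady state
#' with time constant 1/D, and applies measurement noise per the scenario.
#'
#' @param scenario A [sim_scenario()] with `mode = "chemostat"`.
#' @param registry Compound registry.
#' @return A `chemostat_sim` list: `gas` ([gas_series()]), `liquid` (data
#'   frame), `truth` (configured fluxes and expected recoveries), `flows`
#'   (noise-free outlet molar flows), `inlet` (mol/h), `scenario`.
#' @export
simulate_chemostat <- function(scenario, registry = default_registry()) {
  stopifnot(inherits(scenario, "sim_scenario"),
            scenario$mode == "chemostat")
  sc <- scenario
  sug <- sugar_carbon(sc, registry)
  s_flux <- sug$flux_cmol_h

  gamma_s <- mean(gamma_of(names(sc$sugar_feed), registry))
  gp <- gamma_of(names(sc$base_yields), registry)
  gx <- unname(gamma_of("biomass", registry))

  # Base heterotrophic fermentation, closed on carbon and electrons.
  y_co2_0 <- 1 - sum(sc$base_yields) - sc$biomass_yield
  if (y_co2_0 < 0) {
    stop("conservation violation: base product + biomass carbon exceeds sugar carbon")
  }
  h2_y0 <- (gamma_s - sum(sc$base_yields * gp) - sc$biomass_yield * gx) / 2
  if (h2_y0 < 0) {
    stop("conservation violation: base product electrons exceed sugar electrons")
  }

  # Solventogenic shift: butyrate -> butanol, 2 C-mol per mol H2 diverted.
  yields <- sc$base_yields
  z <- 2 * sc$solvent_shift_h2
  if (z > yields[["butyrate"]]) {
    stop("solvent shift exceeds available butyrate yield (needs ", z,
         " C-mol/C-mol, have ", yields[["butyrate"]], ")")
  }
  yields[["butyrate"]] <- yields[["butyrate"]] - z
  yields[["butanol"]] <- yields[["butanol"]] + z
  h2_y <- h2_y0 - sc$solvent_shift_h2

  # Inlet gas.
  inlet_pct <- c(o2 = 0, co = sc$blend[["co"]] * sc$syngas_fraction / 100,
                 co2 = sc$blend[["co2"]] * sc$syngas_fraction / 100,
                 h2 = sc$blend[["h2"]] * sc$syngas_fraction / 100, ar = 0)
  inlet_pct["n2"] <- 100 - sum(inlet_pct)
  inlet <- lapply(GAS_CHANNELS, function(g) {
    fraction_to_molar_flow(inlet_pct[[g]], sc$sparge_flow_l_h,
                           sc$temperature_c, sc$pressure_atm)
  })
  names(inlet) <- GAS_CHANNELS

  e_co2 <- y_co2_0 * s_flux          # endogenous CO2 production, mol/h
  e_h2_avail <- h2_y * s_flux        # endogenous H2 after the shift, mol/h

  regime <- if (sc$syngas_fraction == 0) {
    "heterotrophic"
  } else if (inlet_pct[["co2"]] < sc$co2_switch_threshold) {
    "co_oxidation"
  } else {
    "c1_assimilation"
  }
  if (sc$c1_fraction > 0 && regime != "c1_assimilation") {
    stop("C-1 assimilation requires the assimilation regime (sparged CO2 ",
         "above the switch threshold); regime is '", regime, "'")
  }

  up_co2 <- up_co <- up_h2 <- d_c1 <- co_ox <- 0
  extra <- c(butanol = 0, butyrate = 0)
  if (regime == "co_oxidation") {
    co_ox <- sc$co_ox_fraction * inlet$co
  } else if (regime == "c1_assimilation" && sc$c1_fraction > 0) {
    phi <- sc$c1_fraction * s_flux
    extra <- c(butanol = sc$c1_butanol_share * phi,
               butyrate = (1 - sc$c1_butanol_share) * phi)
    gamma_extra <- sc$c1_butanol_share * gp[["butanol"]] +
      (1 - sc$c1_butanol_share) * gp[["butyrate"]]
    up_co <- sc$c1_co_share * phi
    up_co2 <- phi - up_co
    if (up_co2 > inlet$co2 || up_co > inlet$co) {
      stop("conservation violation: configured C-1 uptake exceeds gas supply")
    }
    n_e <- gamma_extra * phi                       # electron demand
    e_from_co <- 2 * up_co
    up_h2 <- min(sc$h2_uptake_max_fraction * inlet$h2,
                 max(0, (n_e - e_from_co) / 2))
    d_c1 <- (n_e - e_from_co - 2 * up_h2) / 2      # endogenous suppression
    if (d_c1 > e_h2_avail + 1e-12) {
      stop("conservation violation: C-1 electron demand exceeds H2 and ",
           "endogenous electron supply")
    }
  }

  # Steady-state outlet flows (mol/h).
  out <- list(
    o2 = inlet$o2, n2 = inlet$n2, ar = inlet$ar,
    co = inlet$co - up_co - co_ox,
    co2 = inlet$co2 + e_co2 + co_ox - up_co2,
    h2 = inlet$h2 + (e_h2_avail - d_c1) + co_ox - up_h2
  )
  if (any(unlist(out) < -1e-12)) {
    stop("scenario drives an outlet flow negative; reduce uptake fractions")
  }

  # Liquid steady state, g/L.
  total_sugar_cmol <- sum(sug$consumed_cmol_l)
  prod_names <- names(yields)
  conc <- vapply(prod_names, function(p) {
    cmp <- registry[[p]]
    extra_y <- if (p %in% names(extra) && s_flux > 0) {
      extra[[p]] / s_flux
    } else 0
    (yields[[p]] + extra_y) * total_sugar_cmol * cmp$molar_mass /
      cmp$atoms[["C"]]
  }, numeric(1))
  biomass_g_l <- sc$biomass_yield * total_sugar_cmol *
    registry$biomass$molar_mass / 1

  conservation_check(sc, registry, s_flux, yields, extra, inlet, out,
                     e_co2, e_h2_avail, d_c1, up_co, up_co2, up_h2, co_ox,
                     gamma_s, gp, gx)

  # Series on the time grid: biological rates settle with time constant 1/D.
  t <- seq(0, sc$duration_h, by = sc$dt_h)
  settle <- if (isTRUE(sc$start_at_steady)) {
    rep(1, length(t))
  } else {
    1 - exp(-sc$dilution_rate * t)
  }
  flow_mat <- sapply(GAS_CHANNELS, function(g) {
    inlet[[g]] + (out[[g]] - inlet[[g]]) * settle
  })
  total_flow_mol <- rowSums(flow_mat)
  frac_mat <- 100 * flow_mat / total_flow_mol
  flow_l_h <- total_flow_mol * R_GAS_L_ATM * (sc$temperature_c + 273.15) /
    sc$pressure_atm
  fr <- as.data.frame(frac_mat)
  names(fr) <- GAS_COLUMNS
  gas <- gas_series(t, fr, flow_l_h, sc$temperature_c, sc$pressure_atm)

  liquid <- data.frame(time_h = t)
  for (s in names(sc$sugar_feed)) {
    resid <- sc$sugar_feed[[s]] * (1 - sc$sugar_consumed_fraction)
    liquid[[paste0(s, "_g_l")]] <- sc$sugar_feed[[s]] -
      (sc$sugar_feed[[s]] - resid) * settle
  }
  for (p in prod_names) {
    liquid[[paste0(p, "_g_l")]] <- conc[[p]] * settle
  }
  liquid$biomass_g_l <- biomass_g_l * settle

  gamma_extra_mean <- if (sum(extra) > 0) {
    (extra[["butanol"]] * gp[["butanol"]] +
       extra[["butyrate"]] * gp[["butyrate"]]) / sum(extra)
  } else 0
  truth <- list(
    regime = regime,
    sugar_flux_cmol_h = s_flux,
    sugar_consumed_cmol_l = sug$consumed_cmol_l,
    gamma_s = gamma_s,
    yields = yields, biomass_yield = sc$biomass_yield,
    y_co2_0 = y_co2_0, h2_yield_base = h2_y0, h2_yield_net = h2_y,
    e_co2_mol_h = e_co2, e_h2_mol_h = e_h2_avail - d_c1,
    uptake_mol_h = c(co2 = up_co2, co = up_co, h2 = up_h2),
    endogenous_suppression_mol_h = d_c1,
    co_oxidation_mol_h = co_ox,
    extra_product_flux_cmol_h = extra,
    c1_fraction = sc$c1_fraction,
    expected_carbon_recovery = 1 + sc$c1_fraction,
    expected_electron_recovery = 1 +
      (2 * sc$solvent_shift_h2 + gamma_extra_mean * sc$c1_fraction) / gamma_s,
    expected_excess_carbon_pct = 100 * sc$c1_fraction,
    expected_excess_electron_pct = 100 *
      (2 * sc$solvent_shift_h2 + gamma_extra_mean * sc$c1_fraction) / gamma_s,
    inlet_pct = inlet_pct
  )

  sim <- structure(list(gas = gas, liquid = liquid, truth = truth,
                        flows = data.frame(time_h = t, flow_mat),
                        inlet = inlet, scenario = sc),
                   class = "chemostat_sim")
  add_measurement_noise(sim, seed = sc$seed)
}

# Carbon and electron conservation of the configured steady state, to 1e-9.
conservation_check <- function(sc, registry, s_flux, yields, extra, inlet,
                               out, e_co2, e_h2_avail, d_c1, up_co, up_co2,
                               up_h2, co_ox, gamma_s, gp, gx) {
  prod_c <- s_flux * (sum(yields) + sc$biomass_yield) + sum(extra)
  c_in <- s_flux + inlet$co + inlet$co2
  c_out <- prod_c + out$co + out$co2
  if (abs(c_in - c_out) > 1e-9 * max(c_in, 1)) {
    stop("internal carbon conservation failure: in ", c_in, " out ", c_out)
  }
  prod_e <- s_flux * (sum(yields * gp) + sc$biomass_yield * gx) +
    extra[["butanol"]] * gp[["butanol"]] + extra[["butyrate"]] * gp[["butyrate"]]
  e_in <- gamma_s * s_flux + 2 * inlet$co + 2 * inlet$h2
  e_out <- prod_e + 2 * out$co + 2 * out$h2
  if (abs(e_in - e_out) > 1e-9 * max(e_in, 1)) {
    stop("internal electron conservation failure: in ", e_in, " out ", e_out)
  }
  invisible(TRUE)
}

#' Simulate a fed-batch run with gas oscillations
#'
#' Piecewise-exponential biomass growth with a diauxic specific-growth-rate
#' break (`fb_mu1` -> `fb_mu2` at `fb_break_h`, capped at `fb_xmax`),
#' growth-proportional H2/CO2 emission ramps, and a bounded phenomenological
#' limit cycle (amplitude envelope saturating over one period) that activates
#' when the emission fractions cross the onset threshold. Fed volume rises
#' linearly over the run.
#'
#' @param scenario A [sim_scenario()] with `mode = "fedbatch"`.
#' @return A `fedbatch_sim` list: `gas`, `liquid`, `truth`, `scenario`.
#' @export
simulate_fedbatch <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"), scenario$mode == "fedbatch")
  sc <- scenario
  t <- seq(0, sc$fb_duration_h, by = sc$fb_dt_h)
  x_break <- sc$fb_x0 * exp(sc$fb_mu1 * sc$fb_break_h)
  x <- ifelse(t <= sc$fb_break_h,
              sc$fb_x0 * exp(sc$fb_mu1 * t),
              x_break * exp(sc$fb_mu2 * (t - sc$fb_break_h)))
  x <- pmin(x, sc$fb_xmax)

  base <- sc$fb_gas_per_x * x  # %v/v, both gases growth-proportional

  # Analytic onset: base ramp crossing of the onset fraction.
  x_cross <- sc$onset_pct / sc$fb_gas_per_x
  onset_h <- if (x_cross > sc$fb_xmax) {
    NA_real_
  } else if (x_cross <= x_break) {
    log(x_cross / sc$fb_x0) / sc$fb_mu1
  } else {
    sc$fb_break_h + log(x_cross / x_break) / sc$fb_mu2
  }

  osc <- rep(0, length(t))
  if (!is.na(onset_h) && sc$osc_amplitude_pct > 0) {
    after <- t >= onset_h
    env <- pmin(1, (t[after] - onset_h) / sc$osc_period_h)
    osc[after] <- sc$osc_amplitude_pct * env *
      sin(2 * pi * (t[after] - onset_h) / sc$osc_period_h)
  }
  h2 <- pmax(0, base + osc)
  co2 <- pmax(0, base + osc)

  fr <- data.frame(o2_pct = 0, n2_pct = 100 - h2 - co2, co_pct = 0,
                   co2_pct = co2, h2_pct = h2, ar_pct = 0)
  gas <- gas_series(t, fr, sc$sparge_flow_l_h, sc$temperature_c,
                    sc$pressure_atm)

  sucrose0 <- 60
  liquid <- data.frame(
    time_h = t,
    sucrose_g_l = sucrose0 * (1 - 0.6 * x / sc$fb_xmax),
    butanol_g_l = 1.2 * x,
    biomass_g_l = x,
    volume_l = 1 + 0.4 * t / sc$fb_duration_h)

  truth <- list(onset_h = onset_h, period_h = sc$osc_period_h,
                amplitude_pct = sc$osc_amplitude_pct,
                break_h = sc$fb_break_h, mu1 = sc$fb_mu1, mu2 = sc$fb_mu2)
  sim <- structure(list(gas = gas, liquid = liquid, truth = truth,
                        scenario = sc),
                   class = "fedbatch_sim")
  add_measurement_noise(sim, seed = sc$seed)
}

#' Superimpose nitrite-pulse transients on a chemostat simulation
#'
#' For each scheduled dose below the washout threshold, a gamma-shaped
#' transient (time constant `pulse_tau_h`, unit integral) displaces CO uptake
#' by `co_per_no2` mol per mol NO2 in total, adds `h2_per_no2` mol extra H2
#' uptake per mol NO2, and raises the biomass plateau by `biomass_per_no2`
#' grams per mmol. Doses above the threshold trigger exponential biomass
#' washout at rate D and are flagged, not analyzed. Transient windows (one
#' residence time each) must not overlap.
#'
#' @param sim A noise-free `chemostat_sim` (generate with zero noise; noise
#'   is applied here after injection).
#' @param schedule Data frame with `time_h` and `conc_mM`.
#' @param seed Seed for the post-injection measurement noise (default from
#'   the scenario).
#' @return The modified `chemostat_sim`; `truth$pulses` records each event
#'   and the configured stoichiometries.
#' @export
inject_nitrite_pulses <- function(sim, schedule, seed = NULL) {
  stopifnot(inherits(sim, "chemostat_sim"),
            all(c("time_h", "conc_mM") %in% names(schedule)))
  sc <- sim$scenario
  if (sc$noise_gas_pct > 0 || sc$noise_liquid_g_l > 0 ||
      sc$noise_biomass_g_l > 0) {
    # The stored series already carry noise; rebuild noise-free first.
    clean_sc <- sc
    clean_sc$noise_gas_pct <- clean_sc$noise_liquid_g_l <-
      clean_sc$noise_biomass_g_l <- 0
    sim <- simulate_chemostat(clean_sc)
    sim$scenario <- sc
  }
  schedule <- schedule[order(schedule$time_h), , drop = FALSE]
  tau_r <- 1 / sc$dilution_rate
  settle_h <- 3 * tau_r
  if (any(schedule$time_h < settle_h)) {
    stop("pulses must come after the steady state is established (>= ",
         round(settle_h, 1), " h)")
  }
  if (any(diff(schedule$time_h) < tau_r)) {
    stop("overlapping transients: pulses must be at least one residence ",
         "time (", round(tau_r, 1), " h) apart")
  }
  t <- sim$flows$time_h
  flows <- sim$flows
  liquid <- sim$liquid
  events <- list()
  for (i in seq_len(nrow(schedule))) {
    ev <- pulse_event(schedule$time_h[i], schedule$conc_mM[i],
                      sc$volume_l, sc$washout_mM)
    events[[i]] <- ev
    s <- t - ev$time_h
    if (ev$washout) {
      decay <- ifelse(s > 0, exp(-sc$dilution_rate * s), 1)
      liquid$biomass_g_l <- liquid$biomass_g_l * decay
      next
    }
    dose_mol <- ev$dose_mmol / 1000
    g <- ifelse(s > 0, s / sc$pulse_tau_h^2 * exp(-s / sc$pulse_tau_h), 0)
    flows$co <- flows$co + sc$co_per_no2 * dose_mol * g
    flows$h2 <- flows$h2 - sc$h2_per_no2 * dose_mol * g
    if (any(flows$h2 < 0)) {
      stop("pulse at ", ev$time_h, " h drives outlet H2 negative; ",
           "spread the transient (larger pulse_tau_h) or lower the dose")
    }
    liquid$biomass_g_l <- liquid$biomass_g_l +
      sc$biomass_per_no2 * ev$dose_mmol / sc$volume_l *
      ifelse(s > 0, 1 - exp(-s / sc$pulse_tau_h), 0)
  }
  flow_mat <- as.matrix(flows[GAS_CHANNELS])
  total_mol <- rowSums(flow_mat)
  fr <- as.data.frame(100 * flow_mat / total_mol)
  names(fr) <- GAS_COLUMNS
  flow_l_h <- total_mol * R_GAS_L_ATM * (sc$temperature_c + 273.15) /
    sc$pressure_atm
  sim$gas <- gas_series(t, fr, flow_l_h, sc$temperature_c, sc$pressure_atm)
  sim$flows <- flows
  sim$liquid <- liquid
  sim$truth$pulses <- list(
    events = events,
    h2_per_no2 = sc$h2_per_no2, co_per_no2 = sc$co_per_no2,
    biomass_per_no2 = sc$biomass_per_no2)
  add_measurement_noise(sim, seed = seed %||% sc$seed)
}

#' Apply Gaussian measurement noise to a simulation or series
#'
#' Adds iid Gaussian noise per channel (gas fractions, liquid concentrations,
#' biomass), truncated at physical bounds (fractions and concentrations stay
#' nonnegative), bit-reproducible under the seed. With all SDs zero the input
#' is returned unchanged and the RNG is untouched.
#'
#' @param sim A `chemostat_sim` or `fedbatch_sim`.
#' @param noise_gas_pct,noise_liquid_g_l,noise_biomass_g_l SDs; default from
#'   the scenario.
#' @param seed RNG seed; default from the scenario.
#' @return The simulation with noisy `gas` and `liquid` series (truth and
#'   noise-free flows untouched).
#' @export
add_measurement_noise <- function(sim, noise_gas_pct = NULL,
                                  noise_liquid_g_l = NULL,
                                  noise_biomass_g_l = NULL, seed = NULL) {
  sc <- sim$scenario
  sd_gas <- noise_gas_pct %||% sc$noise_gas_pct
  sd_liq <- noise_liquid_g_l %||% sc$noise_liquid_g_l
  sd_bio <- noise_biomass_g_l %||% sc$noise_biomass_g_l
  stopifnot(sd_gas >= 0, sd_liq >= 0, sd_bio >= 0)
  if (sd_gas == 0 && sd_liq == 0 && sd_bio == 0) return(sim)
  seed <- seed %||% sc$seed
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (sd_gas > 0) {
    for (col in GAS_COLUMNS) {
      sim$gas[[col]] <- pmax(0, sim$gas[[col]] +
                               stats::rnorm(nrow(sim$gas), 0, sd_gas))
    }
  }
  liq_cols <- setdiff(names(sim$liquid),
                      c("time_h", "volume_l", "biomass_g_l"))
  if (sd_liq > 0) {
    for (col in liq_cols) {
      sim$liquid[[col]] <- pmax(0, sim$liquid[[col]] +
                                  stats::rnorm(nrow(sim$liquid), 0, sd_liq))
    }
  }
  if (sd_bio > 0) {
    sim$liquid$biomass_g_l <- pmax(0, sim$liquid$biomass_g_l +
                                     stats::rnorm(nrow(sim$liquid), 0, sd_bio))
  }
  sim
}
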