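# Independent oracles and small fixture builders used across the suite.

# Degree of reduction by brute-force atom balance of the combustion
# half-reaction CxHyOzNw + a O2 -> x CO2 + (y-3w)/2 H2O + w NH3:
# oxygen balance gives a, and 4 electrons pass to each O2.
oracle_gamma <- function(compound) {
  a <- compound$atoms
  o2 <- a[["C"]] + a[["H"]] / 4 - a[["O"]] / 2 - 3 * a[["N"]] / 4
  electrons <- 4 * o2
  if (a[["C"]] > 0) electrons / a[["C"]] else electrons
}

# Constant-composition gas series (fractions in %v/v, named by channel).
flat_gas_series <- function(fractions, hours = 40, dt = 0.5,
                            flow = 12.48) {
  t <- seq(0, hours, by = dt)
  full <- c(o2 = 0, n2 = 0, co = 0, co2 = 0, h2 = 0, ar = 0)
  full[names(fractions)] <- fractions
  full["n2"] <- 100 - sum(full[setdiff(names(full), "n2")])
  fr <- as.data.frame(as.list(stats::setNames(full, paste0(names(full),
                                                           "_pct"))))
  gas_series(t, fr[rep(1, length(t)), ], flow)
}

# A feasible random chemostat scenario (used for conservation sweeps).
random_scenario <- function(seed) {
  set.seed(seed)
  repeat {
    y <- stats::runif(5, 0.01, 0.3)
    y <- y / sum(y) * stats::runif(1, 0.3, 0.6)
    names(y) <- c("butanol", "butyrate", "acetate", "acetone", "ethanol")
    yx <- stats::runif(1, 0.05, 0.2)
    if (sum(y) + yx > 0.9) next
    reg <- default_registry()
    gp <- gamma_of(names(y), reg)
    h2_y0 <- (4 - sum(y * gp) - yx * 4.2) / 2
    if (h2_y0 < 0.02) next
    kind <- sample(c("het", "ox", "c1"), 1)
    syngas <- switch(kind, het = 0, ox = stats::runif(1, 5, 20),
                     c1 = stats::runif(1, 30, 80))
    c1 <- if (kind == "c1") stats::runif(1, 0, 0.06) else 0
    shift <- stats::runif(1, 0, min(0.3 * h2_y0, y[["butyrate"]] / 2 * 0.5))
    sc <- try(sim_scenario(
      syngas_fraction = syngas, base_yields = y, biomass_yield = yx,
      c1_fraction = c1, solvent_shift_h2 = shift,
      c1_co_share = stats::runif(1, 0, 0.8),
      sugar_consumed_fraction = stats::runif(1, 0.6, 0.98),
      duration_h = 40, dt_h = 1, seed = seed), silent = TRUE)
    if (inherits(sc, "try-error")) next
    sim <- try(simulate_chemostat(sc), silent = TRUE)
    if (!inherits(sim, "try-error")) return(sim)
  }
}

# External carbon/electron bookkeeping of a noise-free chemostat simulation,
# recomputed from the emitted series and inlet (not from generator internals).
conservation_gap <- function(sim) {
  reg <- default_registry()
  sc <- sim$scenario
  last <- nrow(sim$flows)
  liquid_ss <- sim$liquid[nrow(sim$liquid), ]
  d <- sc$dilution_rate * sc$volume_l
  prod_cols <- grep("_g_l$", names(liquid_ss), value = TRUE)
  c_prod <- e_prod <- 0
  for (col in prod_cols) {
    name <- sub("_g_l$", "", col)
    cmp <- reg[[name]]
    if (is.null(cmp) || cmp$role == "substrate") next
    cmol <- liquid_ss[[col]] / cmp$molar_mass * cmp$atoms[["C"]] * d
    c_prod <- c_prod + cmol
    e_prod <- e_prod + cmol * degree_of_reduction(cmp)
  }
  s_in <- sum(vapply(names(sc$sugar_feed), function(s) {
    cmp <- reg[[s]]
    (sc$sugar_feed[[s]] - liquid_ss[[paste0(s, "_g_l")]]) /
      cmp$molar_mass * cmp$atoms[["C"]]
  }, numeric(1))) * d
  fl <- sim$flows[last, ]
  c_in <- s_in + sim$inlet$co + sim$inlet$co2
  c_out <- c_prod + fl$co + fl$co2
  e_in <- 4 * s_in + 2 * sim$inlet$co + 2 * sim$inlet$h2
  e_out <- e_prod + 2 * fl$co + 2 * fl$h2
  c(carbon = abs(c_in - c_out) / max(c_in, 1e-12),
    electron = abs(e_in - e_out) / max(e_in, 1e-12))
}
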