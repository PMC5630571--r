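#!/usr/bin/env Rscript
# Generate the synthetic study set: a heterotrophic (N2-sparged) chemostat
# control, the three syngas-blend conditions (9 / 32 / 60%), a fed-batch run
# with H2/CO2 oscillations, and a nitrite-pulse experiment on the high-syngas
# steady state. Writes gas/liquid CSVs and scenario YAMLs under
# scratch/sim_data/ (regenerable intermediates); downstream drivers read them
# from there and write their summary tables under results/.

library(mixocarb)

out <- "scratch/sim_data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

save_run <- function(sim, name) {
  write_gas_series(sim$gas, file.path(out, paste0(name, "_gas.csv")))
  write_liquid_series(sim$liquid, file.path(out, paste0(name, "_liquid.csv")))
  write_scenario(sim$scenario, file.path(out, paste0(name, "_scenario.yml")))
  truth <- sim$truth
  flat <- truth[vapply(truth, function(x) is.numeric(x) && length(x) == 1,
                       logical(1))]
  utils::write.csv(data.frame(quantity = names(flat),
                              value = unlist(flat)),
                   file.path(out, paste0(name, "_truth.csv")),
                   row.names = FALSE)
  invisible(sim)
}

cat("== chemostat conditions (D = 0.135 1/h, 12.48 L/h sparge) ==\n")
runs <- list(
  control = scenario_heterotrophic(seed = 101),
  low_syngas = scenario_low_syngas(seed = 102),
  medium_syngas = scenario_medium_syngas(seed = 103),
  high_syngas = scenario_high_syngas(seed = 104)
)
for (name in names(runs)) {
  sim <- save_run(simulate_chemostat(runs[[name]]), name)
  cat(sprintf("  %-14s regime %-16s C-1 fraction %.2f\n", name,
              sim$truth$regime, sim$truth$c1_fraction))
}

cat("\n== fed-batch run with gas oscillations ==\n")
fb <- simulate_fedbatch(sim_scenario(mode = "fedbatch", fb_duration_h = 45,
                                     seed = 105))
save_run(fb, "fedbatch")
cat(sprintf("  oscillation onset at %.2f h (threshold %.1f %%v/v), period %.1f h\n",
            fb$truth$onset_h, fb$scenario$onset_pct, fb$truth$period_h))

cat("\n== nitrite pulses on the high-syngas steady state ==\n")
pulse_sc <- scenario_high_syngas(duration_h = 70, start_at_steady = TRUE,
                                 noise_gas_pct = 0.05, seed = 106)
schedule <- data.frame(time_h = c(30, 45, 60), conc_mM = c(3.1, 6.2, 12.4))
psim <- inject_nitrite_pulses(simulate_chemostat(pulse_sc), schedule)
save_run(psim, "pulses")
utils::write.csv(schedule, file.path(out, "pulses_schedule.csv"),
                 row.names = FALSE)
cat(sprintf("  %d pulses injected (%s mM)\n", nrow(schedule),
            paste(schedule$conc_mM, collapse = "/")))

cat("\nAll series written to", out, "\n")
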