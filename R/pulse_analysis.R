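# Transient responses to nitrite pulses and the electron-sink stoichiometry
# estimated by dose-response regression. Nitrite is an alternative,
# energetically cheaper electron acceptor: a pulse transiently displaces CO
# uptake, increases H2 consumption, and raises the biomass plateau; the
# slopes of those responses against dose are the stoichiometries.

#' Construct a nitrite pulse event
#'
#' @param time_h Pulse time, h.
#' @param conc_mM Final nitrite concentration reached in the broth, mM.
#' @param volume_l Culture volume, L (0.7 for the reference chemostat).
#' @param washout_mM Concentrations above this are toxic and lead to washout;
#'   such events are flagged and excluded from regression, not analyzed.
#' @return A `pulse_event` list with `time_h`, `dose_mmol`, `washout`.
#' @export
pulse_event <- function(time_h, conc_mM, volume_l = 0.7, washout_mM = 24) {
  stopifnot(conc_mM > 0, volume_l > 0)
  structure(list(time_h = time_h, conc_mM = conc_mM,
                 dose_mmol = conc_mM * volume_l,
                 washout = conc_mM > washout_mM),
            class = "pulse_event")
}

#' Gas uptake series relative to inlet and endogenous baseline
#'
#' Converts an off-gas series into per-gas net consumption time courses,
#' u_g(t) = I_g + E_g - O_g(t) (mol/h, positive = consumed), the form the
#' pulse integrals are computed on.
#'
#' @param gas A [gas_series()].
#' @param inlet_pct Named inlet composition, %v/v.
#' @param endogenous Named endogenous production rates E_g (mol/h), e.g. from
#'   [endogenous_baseline()]; missing gases are 0.
#' @param inlet_flow_l_h Sparge flow, L/h (see [inlet_flows()]).
#' @return Data frame `time_h` plus one uptake column per gas channel.
#' @export
uptake_series <- function(gas, inlet_pct, endogenous = numeric(0),
                          inlet_flow_l_h = NULL) {
  flows <- molar_flows(gas)
  inlet <- inlet_flows(inlet_pct, gas, inlet_flow_l_h)
  out <- data.frame(time_h = flows$time_h)
  for (g in GAS_CHANNELS) {
    e <- if (g %in% names(endogenous)) endogenous[[g]] else 0
    out[[g]] <- net_gas_consumption(flows[[g]], inlet[[g]], e)
  }
  out
}

#' Quantify the transient response to one nitrite pulse
#'
#' Integrates the deviation of CO and H2 uptake from their pre-pulse baseline
#' over a response window running from the pulse to the first return within
#' `return_se` baseline standard errors (with a relative floor of
#' `rel_floor` of the peak deviation for noise-free data), capped at one
#' residence time. Displaced CO is the integral of (baseline uptake -
#' observed uptake); extra H2 is the integral of (observed - baseline).
#' The biomass increase is the post-transient plateau minus the pre-pulse
#' mean. If the transient has not returned to baseline by the cap, the result
#' is flagged as a partial integration.
#'
#' @param uptake Data frame from [uptake_series()].
#' @param biomass Data frame with `time_h` and `biomass_g_l`.
#' @param event A [pulse_event()].
#' @param baseline A `steady_state_record` summarizing the pre-pulse uptake
#'   series (variables `co`, `h2`) and `biomass_g_l`.
#' @param dilution_rate Dilution rate, 1/h (sets the window cap 1/D).
#' @param volume_l Culture volume, L (for the biomass increase in grams).
#' @param return_se Return-to-baseline tolerance in baseline SEs.
#' @param rel_floor Relative floor of the return tolerance, as a fraction of
#'   the peak deviation.
#' @return A `pulse_response` list: `dose_mmol`, `displaced_co_mol`,
#'   `extra_h2_mol`, `biomass_increase_g`, `window_h`, `partial`, `washout`.
#' @export
quantify_pulse_response <- function(uptake, biomass, event, baseline,
                                    dilution_rate, volume_l = 0.7,
                                    return_se = 2, rel_floor = 0.02) {
  stopifnot(inherits(event, "pulse_event"),
            inherits(baseline, "steady_state_record"))
  if (event$washout) {
    return(structure(list(dose_mmol = event$dose_mmol, washout = TRUE),
                     class = "pulse_response"))
  }
  t <- uptake$time_h
  cap <- event$time_h + 1 / dilution_rate
  base <- function(v) baseline$mean[match(v, baseline$variable)]
  base_se <- function(v) baseline$se[match(v, baseline$variable)]

  dev_co <- base("co") - uptake$co     # displacement: uptake falls below base
  dev_h2 <- uptake$h2 - base("h2")     # extra consumption above base
  in_win <- t >= event$time_h & t <= cap
  # Return-to-baseline: both deviations inside tolerance after the peak.
  tol_co <- max(return_se * base_se("co"), rel_floor * max(abs(dev_co[in_win])))
  tol_h2 <- max(return_se * base_se("h2"), rel_floor * max(abs(dev_h2[in_win])))
  idx <- which(in_win)
  peak_at <- idx[which.max(pmax(abs(dev_co[idx]), abs(dev_h2[idx])))]
  returned <- idx[idx > peak_at &
                    abs(dev_co[idx]) <= tol_co & abs(dev_h2[idx]) <= tol_h2]
  partial <- length(returned) == 0
  t_end <- if (partial) cap else t[returned[1]]
  seg <- t >= event$time_h & t <= t_end

  displaced_co <- pracma::trapz(t[seg], dev_co[seg])
  extra_h2 <- pracma::trapz(t[seg], dev_h2[seg])

  pre <- biomass$biomass_g_l[biomass$time_h < event$time_h &
                               biomass$time_h >= event$time_h - 1 / dilution_rate]
  post <- biomass$biomass_g_l[biomass$time_h > t_end & biomass$time_h <= cap + 2]
  if (length(post) == 0) post <- utils::tail(biomass$biomass_g_l[biomass$time_h <= cap], 3)
  biomass_increase <- (mean(post) - mean(pre)) * volume_l

  structure(list(
    dose_mmol = event$dose_mmol,
    displaced_co_mol = displaced_co,
    extra_h2_mol = extra_h2,
    biomass_increase_g = biomass_increase,
    window_h = c(event$time_h, t_end),
    partial = partial,
    washout = FALSE
  ), class = "pulse_response")
}

#' Electron-sink stoichiometry by dose-response regression
#'
#' Ordinary least squares of each response against nitrite dose across pulse
#' events, with a fitted (and reported) intercept by default. Slope units:
#' mol gas per mol NO2 for the gas responses (dose in mmol, responses in mol,
#' so the fitted mol/mmol slope is rescaled by 1000), grams per mmol NO2 for
#' biomass. Washout events are excluded and reported.
#'
#' @param responses List of `pulse_response` objects (one per dose).
#' @param intercept Fit an intercept (default `TRUE`). With `FALSE` the
#'   regression is forced through the origin, and a single dose gives r/d.
#' @param conf_level Confidence level for the slope intervals.
#' @return A `stoichiometry_fit` data frame: `response`, `slope`, `se`,
#'   `ci_lo`, `ci_hi`, `intercept`, `unit`; excluded washout doses as an
#'   attribute.
#' @export
stoichiometry_slopes <- function(responses, intercept = TRUE,
                                 conf_level = 0.95) {
  ok <- vapply(responses, function(r) !isTRUE(r$washout), logical(1))
  washed <- vapply(responses[!ok], function(r) r$dose_mmol, numeric(1))
  responses <- responses[ok]
  n_min <- if (intercept) 2 else 1
  if (length(responses) < n_min) {
    stop("need at least ", n_min, " non-washout doses, got ",
         length(responses))
  }
  dose <- vapply(responses, function(r) r$dose_mmol, numeric(1))
  if (length(unique(dose)) < n_min) {
    stop("singular design: all doses equal (", dose[1], " mmol)")
  }
  targets <- list(
    extra_h2_mol = list(label = "h2_per_no2", scale = 1000, unit = "mol/mol"),
    displaced_co_mol = list(label = "co_per_no2", scale = 1000, unit = "mol/mol"),
    biomass_increase_g = list(label = "biomass_per_no2", scale = 1,
                              unit = "g/mmol"))
  rows <- lapply(names(targets), function(field) {
    y <- vapply(responses, function(r) r[[field]], numeric(1))
    fit <- if (intercept) stats::lm(y ~ dose) else stats::lm(y ~ dose - 1)
    # Noise-free fixtures fit exactly; the perfect-fit warning is expected.
    co <- suppressWarnings(summary(fit)$coefficients)
    slope_row <- co["dose", ]
    ci <- suppressWarnings(stats::confint(fit, "dose", level = conf_level))
    sc <- targets[[field]]$scale
    data.frame(
      response = targets[[field]]$label,
      slope = unname(slope_row["Estimate"]) * sc,
      se = unname(slope_row["Std. Error"]) * sc,
      ci_lo = ci[1] * sc, ci_hi = ci[2] * sc,
      intercept = if (intercept) unname(stats::coef(fit)[1]) else 0,
      unit = targets[[field]]$unit)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "washout_doses_mmol") <- washed
  class(out) <- c("stoichiometry_fit", "data.frame")
  out
}
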