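# Chemostat steady-state detection and summary under the three-residence-time
# rule: sampling may not begin before min_residence/D hours after the last
# perturbation, and a window is accepted only when every monitored variable's
# linear trend over the window is negligible relative to its mean.

#' Detect a chemostat steady-state window
#'
#' Scans for the maximal window, starting no earlier than
#' `min_residence / dilution_rate` hours after the last perturbation marker,
#' in which every monitored variable is trend-free: the fitted linear slope
#' times the window length must stay below `rel_tol` of the window mean
#' (variables with near-zero mean are compared on an absolute scale).
#' The window start is advanced in quarter-residence steps until the
#' criterion holds.
#'
#' @param series Data frame with a `time_h` column and one column per
#'   monitored variable (a [gas_series()] works; its `flow_l_h` is ignored).
#' @param dilution_rate Dilution rate D, 1/h; residence time is 1/D.
#' @param min_residence Residence times that must elapse after a perturbation
#'   before sampling (default 3).
#' @param rel_tol Relative trend tolerance (default 0.02: |slope| * length
#'   < 2% of the window mean).
#' @param perturbations Times (h) of perturbation markers (pulses, gas-blend
#'   switches). Markers are explicit inputs, not inferred. The series start is
#'   always treated as a perturbation.
#' @param min_samples Minimum samples an accepted window must contain.
#' @return A `steady_window` list with `start`, `end`,
#'   `residence_times_elapsed` and `n_samples`, or an empty `steady_miss`
#'   object (with a `diagnostic` attribute naming the worst-offending
#'   variable) when no window qualifies; test with [is_steady_window()].
#' @export
detect_steady_state <- function(series, dilution_rate, min_residence = 3,
                                rel_tol = 0.02, perturbations = numeric(0),
                                min_samples = 3) {
  stopifnot(dilution_rate > 0, min_residence >= 0)
  series <- as.data.frame(series)
  vars <- setdiff(names(series), c("time_h", "flow_l_h"))
  t <- series$time_h
  tau <- 1 / dilution_rate
  t0 <- max(c(t[1], perturbations)) + min_residence * tau
  t_end <- t[length(t)]
  if (t_end <= t0) {
    return(steady_miss(sprintf(
      "series ends at %.2f h, before the %d-residence-time mark at %.2f h",
      t_end, min_residence, t0)))
  }
  worst <- NULL
  start <- t0
  while (TRUE) {
    keep <- t >= start
    if (sum(keep) < min_samples || (t_end - start) < tau / 4) break
    offender <- trend_offender(series[keep, , drop = FALSE], vars, rel_tol)
    if (is.null(offender)) {
      return(structure(
        list(start = start, end = t_end,
             residence_times_elapsed = (start - (t0 - min_residence * tau)) /
               tau,
             n_samples = sum(keep)),
        class = "steady_window"))
    }
    worst <- offender
    start <- start + tau / 4
  }
  steady_miss(if (is.null(worst)) {
    "too few samples after the residence-time mark"
  } else {
    sprintf("variable '%s' drifts %.1f%% of its mean over the window (tol %.1f%%)",
            worst$var, 100 * worst$rel_drift, 100 * rel_tol)
  })
}

steady_miss <- function(diagnostic) {
  structure(list(), class = "steady_miss", diagnostic = diagnostic)
}

#' Did steady-state detection find a window?
#'
#' @param x Result of [detect_steady_state()].
#' @return `TRUE` for an accepted `steady_window`.
#' @export
is_steady_window <- function(x) inherits(x, "steady_window")

# Worst trending variable in a window, or NULL if all pass. A variable
# offends only when its drift is both large relative to its mean and
# statistically distinguishable from zero (3 SEs), so noise-dominated or
# near-zero channels do not block detection.
trend_offender <- function(win, vars, rel_tol) {
  t <- win$time_h
  n <- length(t)
  len <- t[n] - t[1]
  sxx <- sum((t - mean(t))^2)
  worst <- NULL
  for (v in vars) {
    y <- win[[v]]
    if (all(!is.finite(y))) next
    slope <- if (sxx == 0) 0 else sum((t - mean(t)) * (y - mean(y))) / sxx
    resid <- y - mean(y) - slope * (t - mean(t))
    se_slope <- if (n > 2 && sxx > 0) {
      sqrt(sum(resid^2) / (n - 2) / sxx)
    } else 0
    scale <- max(abs(mean(y)), 1e-8)
    rel_drift <- abs(slope) * len / scale
    if (rel_drift >= rel_tol && abs(slope) >= 3 * se_slope &&
        (is.null(worst) || rel_drift > worst$rel_drift)) {
      worst <- list(var = v, rel_drift = rel_drift)
    }
  }
  worst
}

#' Summarize a steady-state window
#'
#' Mean, standard error and sample count for every monitored variable over an
#' accepted window. At least three samples are required, mirroring the
#' practice of summarizing a chemostat state from at least three samples taken
#' at different residence-time intervals.
#'
#' @param series Data frame with `time_h` and variable columns.
#' @param window A `steady_window` from [detect_steady_state()].
#' @return A `steady_state_record`: data frame `variable`, `mean`, `se`, `n`
#'   with the window carried as an attribute.
#' @export
summarize_steady_state <- function(series, window) {
  stopifnot(inherits(window, "steady_window"))
  series <- as.data.frame(series)
  keep <- series$time_h >= window$start & series$time_h <= window$end
  n <- sum(keep)
  if (n < 3) stop("steady-state summary requires >= 3 samples, got ", n)
  vars <- setdiff(names(series), "time_h")
  out <- data.frame(
    variable = vars,
    mean = vapply(vars, function(v) mean(series[[v]][keep]), numeric(1)),
    se = vapply(vars, function(v) stats::sd(series[[v]][keep]) / sqrt(n),
                numeric(1)),
    n = n, row.names = NULL)
  attr(out, "window") <- window
  class(out) <- c("steady_state_record", "data.frame")
  out
}

#' Look up a summarized mean
#'
#' @param record A `steady_state_record`.
#' @param variable Variable name.
#' @return Mean value over the window.
#' @export
ss_mean <- function(record, variable) {
  i <- match(variable, record$variable)
  if (is.na(i)) stop("variable '", variable, "' not in steady-state record")
  record$mean[i]
}
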