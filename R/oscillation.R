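# Detection and characterization of synchronous H2/CO2 off-gas oscillations,
# oscillation-onset timing, and the diauxic specific-growth-rate break in
# fed-batch runs.

#' Detect and characterize H2/CO2 oscillations
#'
#' Each series is detrended with a running median, peaks and troughs are
#' located with a prominence threshold of `prominence_mads` times the local
#' noise MAD, and an oscillation is declared when at least `min_cycles`
#' complete cycles are present in both gases. The period is the median
#' inter-peak interval, the amplitude the median peak-to-trough excursion
#' halved. Synchrony is the zero-lag normalized cross-correlation of the
#' detrended series; the phase lag is the argmax of the cross-correlation.
#' The pair is called in-phase when |lag| < `inphase_lag_frac` of the period
#' and synchrony >= `inphase_synchrony` (both configurable: the underlying
#' phenotype is only described qualitatively, so these are reporting
#' thresholds, not biology).
#'
#' @param time_h Uniformly spaced time stamps, h.
#' @param h2,co2 Gas fractions, %v/v, on the common grid.
#' @param min_cycles Minimum complete cycles to declare oscillation.
#' @param detrend_window Running-median window in samples (odd); default about
#'   a tenth of the series.
#' @param prominence_mads Peak prominence threshold in local-noise MADs.
#' @param inphase_lag_frac,inphase_synchrony Thresholds for the in-phase call.
#' @return An `oscillation_report` list: `oscillating`, per-gas `period_h` and
#'   `amplitude_pct`, `lag_h`, `synchrony`, `in_phase`. When no oscillation is
#'   found, `oscillating = FALSE` and the characterization fields are absent.
#' @export
detect_oscillations <- function(time_h, h2, co2, min_cycles = 2,
                                detrend_window = NULL, prominence_mads = 3,
                                inphase_lag_frac = 0.1,
                                inphase_synchrony = 0.8) {
  stopifnot(length(time_h) == length(h2), length(h2) == length(co2))
  dt <- diff(time_h)
  if (max(dt) - min(dt) > 1e-6 * mean(dt)) {
    stop("series must be uniformly resampled before oscillation analysis")
  }
  dt <- mean(dt)
  one_pass <- function(window) {
    window <- min(window, length(time_h) - 2L)
    if (window %% 2 == 0) window <- window + 1L
    d_h2 <- h2 - stats::runmed(h2, window)
    d_co2 <- co2 - stats::runmed(co2, window)
    # Running-median plateaus can split one crest into several local maxima;
    # peaks closer than a quarter of the detrend window are merged.
    sep <- max(1L, window %/% 4L)
    list(d_h2 = d_h2, d_co2 = d_co2,
         ch_h2 = characterize_cycles(time_h, d_h2, prominence_mads,
                                     min_cycles, min_sep = sep),
         ch_co2 = characterize_cycles(time_h, d_co2, prominence_mads,
                                      min_cycles, min_sep = sep))
  }
  pass <- one_pass(detrend_window %||%
                     max(5L, as.integer(length(time_h) / 10)))
  if (!is.null(pass$ch_h2) && !is.null(pass$ch_co2) &&
      is.null(detrend_window)) {
    # Refine: a detrend window of about two periods removes the slow trend
    # without attenuating the cycle itself.
    period0 <- mean(c(pass$ch_h2$period_h, pass$ch_co2$period_h))
    pass <- one_pass(max(5L, as.integer(2 * period0 / dt)))
  }
  ch_h2 <- pass$ch_h2
  ch_co2 <- pass$ch_co2
  d_h2 <- pass$d_h2
  d_co2 <- pass$d_co2
  if (is.null(ch_h2) || is.null(ch_co2)) {
    return(structure(list(oscillating = FALSE), class = "oscillation_report"))
  }

  denom <- sqrt(sum(d_h2^2) * sum(d_co2^2))
  synchrony <- if (denom > 0) sum(d_h2 * d_co2) / denom else 0
  period <- mean(c(ch_h2$period, ch_co2$period))
  max_lag <- max(1L, as.integer(ceiling(period / dt)))
  cc <- stats::ccf(d_h2, d_co2, lag.max = max_lag, plot = FALSE)
  lag_h <- cc$lag[which.max(cc$acf)] * dt

  structure(list(
    oscillating = TRUE,
    h2 = ch_h2, co2 = ch_co2,
    lag_h = lag_h,
    synchrony = synchrony,
    in_phase = abs(lag_h) < inphase_lag_frac * period &&
      synchrony >= inphase_synchrony
  ), class = "oscillation_report")
}

# Period/amplitude of one detrended channel; NULL when < min_cycles regular
# cycles survive the prominence filter. The local-noise threshold is the MAD
# of first differences; peaks are additionally required to be comparable with
# the dominant excursion (guards against detrending curvature residuals in
# smooth non-oscillating stretches) and to recur at regular intervals.
characterize_cycles <- function(time_h, detrended, prominence_mads,
                                min_cycles, min_sep = 1L,
                                max_irregularity = 0.5) {
  detrended <- as.numeric(detrended)
  noise <- stats::mad(diff(detrended)) / sqrt(2)
  height <- prominence_mads * max(noise, .Machine$double.eps)
  peaks <- pracma::findpeaks(detrended, minpeakheight = height,
                             minpeakdistance = min_sep)
  troughs <- pracma::findpeaks(-detrended, minpeakheight = height,
                               minpeakdistance = min_sep)
  if (is.null(peaks) || is.null(troughs)) return(NULL)
  if (nrow(peaks) < min_cycles + 1 || nrow(troughs) < min_cycles) {
    return(NULL)
  }
  peak_t <- sort(time_h[peaks[, 2]])
  intervals <- diff(peak_t)
  if (stats::sd(intervals) > max_irregularity * stats::median(intervals)) {
    return(NULL)
  }
  list(
    period_h = stats::median(intervals),
    amplitude_pct = (stats::median(peaks[, 1]) +
                       stats::median(troughs[, 1])) / 2,
    n_peaks = nrow(peaks)
  )
}

#' @export
print.oscillation_report <- function(x, ...) {
  if (!x$oscillating) {
    cat("<oscillation_report> no oscillation detected\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<oscillation_report> period H2 %.3g h / CO2 %.3g h; amplitude %.3g / %.3g %%v/v\n",
    x$h2$period_h, x$co2$period_h, x$h2$amplitude_pct, x$co2$amplitude_pct))
  cat(sprintf("  lag %.3g h, synchrony %.3f, in phase: %s\n",
              x$lag_h, x$synchrony, x$in_phase))
  invisible(x)
}

#' Oscillation / solventogenesis onset time
#'
#' First crossing of a gas fraction above a threshold (default 3 %v/v, where
#' the synchronous oscillations set in), located by linear interpolation
#' between the bracketing samples. The series must start at or below the
#' threshold.
#'
#' @param time_h Time stamps, h.
#' @param x Gas fraction series, %v/v.
#' @param threshold_pct Onset threshold, %v/v.
#' @return Crossing time (h), or `NA` with a `diagnostic` attribute when the
#'   series never crosses.
#' @export
onset_detection <- function(time_h, x, threshold_pct = 3) {
  stopifnot(length(time_h) == length(x), length(x) >= 2)
  if (x[1] > threshold_pct) {
    stop("series starts above the onset threshold (",
         x[1], " > ", threshold_pct, " %v/v)")
  }
  if (x[1] == threshold_pct) return(time_h[1])
  above <- which(x >= threshold_pct)
  if (length(above) == 0) {
    out <- NA_real_
    attr(out, "diagnostic") <- sprintf(
      "series never reaches %.3g %%v/v (max %.3g)", threshold_pct, max(x))
    return(out)
  }
  i <- above[1]
  t0 <- time_h[i - 1]; t1 <- time_h[i]
  x0 <- x[i - 1]; x1 <- x[i]
  t0 + (threshold_pct - x0) / (x1 - x0) * (t1 - t0)
}

#' Diauxic growth-rate break
#'
#' Fits a two-segment linear model to log-biomass over a grid of candidate
#' breakpoints (each segment keeps at least three points), returning the
#' break time, the specific growth rates before and after, and whether the
#' two-segment fit is a significant improvement over a single exponential
#' (partial F-test at `alpha`).
#'
#' @param time_h Time stamps, h (>= 6 points).
#' @param biomass Biomass series, g/L (strictly positive).
#' @param alpha Significance level for the break call.
#' @return List with `break_time_h`, `mu_before`, `mu_after`, `significant`,
#'   `p_value`.
#' @export
growth_rate_break <- function(time_h, biomass, alpha = 0.05) {
  n <- length(time_h)
  if (n < 6) stop("growth-rate break fit requires >= 6 points, got ", n)
  if (any(biomass <= 0)) stop("biomass must be strictly positive")
  ly <- log(biomass)
  fit1 <- stats::lm(ly ~ time_h)
  rss1 <- sum(stats::residuals(fit1)^2)
  best <- NULL
  for (i in 3:(n - 3)) {
    f_a <- stats::lm(ly[1:i] ~ time_h[1:i])
    f_b <- stats::lm(ly[(i + 1):n] ~ time_h[(i + 1):n])
    rss <- sum(stats::residuals(f_a)^2) + sum(stats::residuals(f_b)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss, i = i,
                   mu_before = unname(stats::coef(f_a)[2]),
                   mu_after = unname(stats::coef(f_b)[2]))
    }
  }
  # Two-segment model spends 2 extra parameters (second slope + intercept).
  df2 <- n - 4
  f_stat <- if (best$rss <= 0) Inf else ((rss1 - best$rss) / 2) / (best$rss / df2)
  p <- stats::pf(f_stat, 2, df2, lower.tail = FALSE)
  list(
    break_time_h = (time_h[best$i] + time_h[best$i + 1]) / 2,
    mu_before = best$mu_before,
    mu_after = best$mu_after,
    significant = is.finite(f_stat) && p < alpha &&
      abs(best$mu_before - best$mu_after) > 1e-8,
    p_value = p
  )
}
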