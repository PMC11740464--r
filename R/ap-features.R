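#' Per-spike action-potential waveform features
#'
#' Implements the standard derivative-based feature set on a single sweep:
#' * threshold: voltage at the maximum of the third time-derivative of V in a
#'   short window just before the spike peak (the window is `window_ms` long,
#'   clipped at the previous spike's AHP minimum); V is smoothed with a
#'   2nd-order local polynomial (Savitzky-Golay) over `smooth_ms` before the
#'   finite-difference derivatives are taken, while the threshold voltage
#'   itself is read from the raw trace at the located sample;
#' * amplitude: peak voltage minus threshold;
#' * half width: time V stays above threshold + amplitude/2, with linearly
#'   interpolated crossings;
#' * AHP: threshold minus the minimum voltage between the peak and the next
#'   spike (for the final spike, up to the end of the step window);
#' * rising / falling slope: extreme first derivative (raw finite
#'   differences) on the upstroke / downstroke, the falling slope reported as
#'   a positive magnitude.
#'
#' @param voltage_mV Numeric vector, one sweep.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param spikes A `spike_train` from [detect_spikes()] for this sweep.
#' @param step_end_ms End of the step window, ms (bound for the final
#'   spike's AHP search); defaults to the end of the trace.
#' @param window_ms Threshold search window before the peak, ms.
#' @param smooth_ms Smoothing span for the derivative estimates, ms.
#'
#' @return Data.frame with one row per detected spike: `threshold_mV`,
#'   `threshold_time_ms`, `amplitude_mV`, `half_width_ms`, `ahp_mV`,
#'   `rise_slope_mV_per_ms`, `fall_slope_mV_per_ms`, `peak_mV`,
#'   `peak_time_ms`, and `ok` (FALSE for spikes with a degenerate
#'   measurement window, whose features are NA).
#' @export
ap_waveform_features <- function(voltage_mV, sample_rate_hz, spikes,
                                 step_end_ms = NULL,
                                 window_ms = 3, smooth_ms = 0.35) {
  v <- as.numeric(voltage_mV)
  n <- length(v)
  dt <- 1000 / sample_rate_hz
  if (is.null(step_end_ms)) step_end_ms <- (n - 1) * dt
  ns <- nrow(spikes)
  if (ns == 0) stop("no spikes in sweep; waveform features undefined")

  vs <- sgolay_smooth(v, sample_rate_hz, smooth_ms)
  d3 <- grad1(grad1(grad1(vs, dt), dt), dt)

  out <- data.frame(
    spike = seq_len(ns), threshold_mV = NA_real_, threshold_time_ms = NA_real_,
    amplitude_mV = NA_real_, half_width_ms = NA_real_, ahp_mV = NA_real_,
    rise_slope_mV_per_ms = NA_real_, fall_slope_mV_per_ms = NA_real_,
    peak_mV = spikes$peak_mV, peak_time_ms = spikes$peak_time_ms,
    ok = FALSE)

  step_end_idx <- min(n, floor(step_end_ms / dt) + 1)
  prev_ahp_idx <- 1L
  for (k in seq_len(ns)) {
    pk <- spikes$peak_idx[k]
    lo <- max(pk - round(window_ms / dt), prev_ahp_idx + 1L, 1L)
    if (pk - lo < 3) next  # degenerate window: features stay NA

    thr_idx <- lo + which.max(d3[lo:pk]) - 1L
    thr <- v[thr_idx]
    amp <- spikes$peak_mV[k] - thr

    # AHP: minimum between this peak and the next spike (or end of step)
    bound <- if (k < ns) spikes$cross_idx[k + 1] else step_end_idx
    if (bound <= pk + 1) next
    seg <- (pk + 1):bound
    ahp_idx <- seg[which.min(v[seg])]
    ahp <- thr - v[ahp_idx]

    level <- thr + amp / 2
    t_up <- cross_time_up(v, thr_idx, pk, level, dt)
    t_down <- cross_time_down(v, pk, bound, level, dt)
    hw <- if (is.na(t_up) || is.na(t_down)) NA_real_ else t_down - t_up

    dv <- diff(v) / dt
    rise <- max(dv[thr_idx:(pk - 1)])
    fall <- abs(min(dv[pk:(ahp_idx - 1L)]))

    out$threshold_mV[k] <- thr
    out$threshold_time_ms[k] <- (thr_idx - 1) * dt
    out$amplitude_mV[k] <- amp
    out$half_width_ms[k] <- hw
    out$ahp_mV[k] <- ahp
    out$rise_slope_mV_per_ms[k] <- rise
    out$fall_slope_mV_per_ms[k] <- fall
    out$ok[k] <- TRUE
    prev_ahp_idx <- ahp_idx
  }
  out
}

# Savitzky-Golay smoothing (2nd-order local polynomial) over `smooth_ms`.
sgolay_smooth <- function(v, sample_rate_hz, smooth_ms) {
  dt <- 1000 / sample_rate_hz
  n_win <- round(smooth_ms / dt)
  if (n_win %% 2 == 0) n_win <- n_win + 1
  n_win <- max(5, n_win)
  if (n_win >= length(v)) return(v)
  as.numeric(signal::sgolayfilt(v, p = 2, n = n_win))
}

# Central-difference gradient, one-sided at the ends; output length matches.
grad1 <- function(x, dt) {
  n <- length(x)
  g <- numeric(n)
  g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  g[1] <- (x[2] - x[1]) / dt
  g[n] <- (x[n] - x[n - 1]) / dt
  g
}

# Last upward crossing of `level` in [i0, i1], linearly interpolated (ms).
cross_time_up <- function(v, i0, i1, level, dt) {
  if (i1 <= i0) return(NA_real_)
  i <- i0:(i1 - 1)
  hit <- i[v[i] < level & v[i + 1] >= level]
  if (!length(hit)) return(NA_real_)
  i <- hit[length(hit)]
  (i - 1) * dt + dt * (level - v[i]) / (v[i + 1] - v[i])
}

# First downward crossing of `level` in [i0, i1], linearly interpolated (ms).
cross_time_down <- function(v, i0, i1, level, dt) {
  if (i1 <= i0) return(NA_real_)
  i <- i0:(i1 - 1)
  hit <- i[v[i] >= level & v[i + 1] < level]
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  (i - 1) * dt + dt * (v[i] - level) / (v[i] - v[i + 1])
}

#' F-I curve: first instantaneous frequency and spike count per amplitude
#'
#' The firing response to increasing current is summarized by plotting the
#' first instantaneous AP frequency (1 / first interspike interval) against
#' the injection amplitude; the frequency is undefined (NA) for sweeps with
#' fewer than two spikes, while the AP count is always reported.
#'
#' @param spike_trains List of `spike_train` objects, one per sweep.
#' @param amplitudes_pA Step amplitudes matching `spike_trains`.
#' @return Data.frame with `amplitude_pA`, `n_spikes`, `f1_hz`.
#' @export
fi_curve <- function(spike_trains, amplitudes_pA) {
  stopifnot(length(spike_trains) == length(amplitudes_pA))
  f1 <- vapply(spike_trains, function(st) {
    if (nrow(st) < 2) NA_real_ else 1000 / (st$time_ms[2] - st$time_ms[1])
  }, numeric(1))
  data.frame(amplitude_pA = amplitudes_pA,
             n_spikes = vapply(spike_trains, nrow, integer(1)),
             f1_hz = f1)
}

#' Spike-frequency adaptation index
#'
#' Ratio of the first over the last instantaneous firing frequency within a
#' current pulse, equal to the last over the first interspike interval.
#' Requires at least three spikes (two intervals); NA otherwise.
#'
#' @param spike_times_ms Spike times within one sweep, ms.
#' @return Numeric scalar (>= 1 for adapting trains), or NA.
#' @export
adaptation_index <- function(spike_times_ms) {
  if (length(spike_times_ms) < 3) return(NA_real_)
  isi <- diff(spike_times_ms)
  isi[length(isi)] / isi[1]
}
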