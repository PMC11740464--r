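#' Configuration for a synthetic network-hyperexcitability trace
#'
#' Describes a long continuous current-clamp recording in which recurrent
#' polysynaptic bursts emerge after a controllable latency, emulating a slice
#' moving into a 0 Mg2+/high-K+ hyperexcitable state: a noisy baseline with
#' sparse small subthreshold synaptic events (< 2 mV) and, from `first_onset_s`
#' on, compound depolarizations of amplitude `burst_amp_mV` recurring every
#' `interval_s` (with onset jitter).
#'
#' @param duration_s Trace duration, s.
#' @param baseline_mV Holding baseline, mV.
#' @param noise_sd_mV Additive white-noise SD, mV.
#' @param psp_rate_hz Rate of small PSP-shaped background events, Hz.
#' @param psp_amp_mV Peak amplitude of background PSPs, mV (must stay below
#'   the 2 mV burst criterion).
#' @param first_onset_s Onset of the first burst, s (NA or Inf for a scene
#'   without bursts).
#' @param interval_s Burst recurrence interval, s.
#' @param onset_jitter_s SD of Gaussian jitter applied to each onset, s.
#' @param burst_amp_mV Burst peak depolarization above baseline, mV (> 2).
#' @param burst_dur_s Burst duration, s.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param seed Integer seed.
#' @return An object of class `burst_scene_config`.
#' @export
burst_scene_config <- function(duration_s = 200, baseline_mV = -65,
                               noise_sd_mV = 0.2, psp_rate_hz = 2,
                               psp_amp_mV = 1, first_onset_s = 60,
                               interval_s = 20, onset_jitter_s = 0,
                               burst_amp_mV = 8, burst_dur_s = 2,
                               sample_rate_hz = 1000, seed = 1) {
  has_bursts <- is.finite(first_onset_s)
  if (has_bursts && burst_amp_mV <= 2)
    stop("`burst_amp_mV` must exceed the 2 mV detection criterion")
  if (psp_amp_mV >= 2)
    stop("`psp_amp_mV` must stay below the 2 mV burst criterion")
  if (has_bursts && first_onset_s + interval_s >= duration_s &&
      first_onset_s < duration_s)
    warning("fewer than two bursts fit in the trace")
  structure(list(duration_s = duration_s, baseline_mV = baseline_mV,
                 noise_sd_mV = noise_sd_mV, psp_rate_hz = psp_rate_hz,
                 psp_amp_mV = psp_amp_mV, first_onset_s = first_onset_s,
                 interval_s = interval_s, onset_jitter_s = onset_jitter_s,
                 burst_amp_mV = burst_amp_mV, burst_dur_s = burst_dur_s,
                 sample_rate_hz = sample_rate_hz, seed = seed),
            class = "burst_scene_config")
}

#' Simulate a continuous trace with emergent polysynaptic bursts
#'
#' @param config A [burst_scene_config()].
#' @return List with `trace` (numeric vector, mV), `sample_rate_hz`, and
#'   `truth` (data.frame of true burst `onset_s` and `amp_mV`; zero rows when
#'   no burst was planted). Time is measured from the trace start.
#' @export
simulate_network_trace <- function(config) {
  stopifnot(inherits(config, "burst_scene_config"))
  set.seed(config$seed)
  fs <- config$sample_rate_hz
  n <- round(config$duration_s * fs)
  v <- rep(config$baseline_mV, n)

  # sparse background PSPs: alpha-shaped, strictly below the burst criterion
  n_psp <- stats::rpois(1, config$psp_rate_hz * config$duration_s)
  psp_tau <- 0.02  # s
  kernel_t <- seq(0, 8 * psp_tau, by = 1 / fs)
  psp_kernel <- (kernel_t / psp_tau) * exp(1 - kernel_t / psp_tau)
  if (n_psp > 0) {
    starts <- sort(stats::runif(n_psp, 0, config$duration_s))
    amps <- stats::runif(n_psp, 0.3, 1) * config$psp_amp_mV
    for (i in seq_len(n_psp)) {
      i0 <- round(starts[i] * fs) + 1
      if (i0 > n) next  # start rounds past the last sample
      idx <- i0:min(n, i0 + length(psp_kernel) - 1)
      v[idx] <- v[idx] + amps[i] * psp_kernel[seq_along(idx)]
    }
  }

  truth <- data.frame(onset_s = numeric(0), amp_mV = numeric(0))
  if (is.finite(config$first_onset_s)) {
    onset <- config$first_onset_s
    while (onset + config$burst_dur_s < config$duration_s) {
      o <- onset + if (config$onset_jitter_s > 0)
        stats::rnorm(1, sd = config$onset_jitter_s) else 0
      o <- max(0, min(o, config$duration_s - config$burst_dur_s))
      bt <- seq(0, config$burst_dur_s, by = 1 / fs)
      env <- config$burst_amp_mV * sin(pi * bt / config$burst_dur_s)^2
      # fast internal oscillation makes the event look compound/polysynaptic
      env <- env * (0.8 + 0.2 * sin(2 * pi * 12 * bt))
      i0 <- round(o * fs) + 1
      idx <- i0:min(n, i0 + length(env) - 1)
      v[idx] <- v[idx] + env[seq_along(idx)]
      truth <- rbind(truth, data.frame(onset_s = o,
                                       amp_mV = config$burst_amp_mV))
      onset <- onset + config$interval_s
    }
  }
  if (config$noise_sd_mV > 0)
    v <- v + stats::rnorm(n, sd = config$noise_sd_mV)
  list(trace = v, sample_rate_hz = fs, truth = truth)
}
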