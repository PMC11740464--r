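# Shared fixtures for the test suite.

# Small, fast protocol: -50 pA (passive), 0 pA (resting), and one
# suprathreshold amplitude 100 pA above the default rheobase.
quick_protocol <- function(sample_rate_hz = 20000) {
  make_step_protocol(start_pA = -50, stop_pA = 300, increment_pA = 50,
                     sample_rate_hz = sample_rate_hz)
}

noise_free_params <- function(...) neuron_params(noise_sd_mV = 0, ...)

# Index of the sweep at a given amplitude.
sweep_at <- function(sweeps, amplitude_pA) {
  which(sweeps$protocol$amplitudes_pA == amplitude_pA)[1]
}

# Run detection + waveform features on one sweep of a sweep_set.
features_for_sweep <- function(sweeps, amplitude_pA, ...) {
  s <- sweep_at(sweeps, amplitude_pA)
  proto <- sweeps$protocol
  v <- sweeps$voltage[, s]
  st <- detect_spikes(v, proto$sample_rate_hz)
  ap_waveform_features(v, proto$sample_rate_hz, st,
                       step_end_ms = proto$pre_ms + proto$step_ms, ...)
}

# 3 x 3 x 3 grid of template parameter combinations used by the
# feature-recovery and oracle-equivalence acceptance checks.
template_grid <- function() {
  expand.grid(VT_mV = c(-50, -45, -40),
              ahp_depth_mV = c(6, 12, 18),
              rise_slope_mV_per_ms = c(250, 400, 550))
}
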