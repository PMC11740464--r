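#' Ground-truth parameters of a synthetic neuron
#'
#' Collects the passive and active parameters from which step-sweep responses
#' are rendered. Subthreshold sweeps follow a single-exponential RC charging
#' curve (`Rin_MOhm`, `tau_m_ms`, `rest_mV`); suprathreshold sweeps carry
#' planted spikes with a piecewise-linear waveform template whose measured
#' features (threshold, amplitude, half width, AHP depth, slopes) are known in
#' closed form. Defaults describe a regular-spiking layer-V pyramidal neuron.
#'
#' @param Rin_MOhm Input resistance, MOhm.
#' @param tau_m_ms Membrane time constant, ms.
#' @param rest_mV Resting / holding baseline potential, mV.
#' @param Ra_MOhm Access resistance recorded with the cell, MOhm (QC metadata).
#' @param rheobase_pA Minimal step current that elicits spiking, pA.
#' @param gain_hz_per_pA Slope of first instantaneous frequency vs current
#'   above rheobase, Hz/pA.
#' @param adapt_rho Per-interval ISI growth factor (>= 1); successive
#'   interspike intervals are `ISI1 * adapt_rho^(k-1)`.
#' @param VT_mV Spike threshold, mV (must be below 0 so every spike crosses
#'   0 mV on the upstroke).
#' @param peak_mV Spike peak, mV (must be above 0).
#' @param rise_slope_mV_per_ms Upstroke slope, mV/ms.
#' @param fall_slope_mV_per_ms Downstroke slope magnitude, mV/ms.
#' @param ahp_depth_mV Depth of the post-spike minimum below threshold, mV.
#' @param ahp_recover_ms Relaxation time from the AHP minimum back to the
#'   inter-spike baseline, ms.
#' @param noise_sd_mV SD of additive white baseline noise, mV.
#'
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(Rin_MOhm = 120, tau_m_ms = 20, rest_mV = -65,
                          Ra_MOhm = 12, rheobase_pA = 200,
                          gain_hz_per_pA = 0.4, adapt_rho = 1.15,
                          VT_mV = -45, peak_mV = 35,
                          rise_slope_mV_per_ms = 400,
                          fall_slope_mV_per_ms = 100,
                          ahp_depth_mV = 12, ahp_recover_ms = 4,
                          noise_sd_mV = 0.1) {
  p <- list(Rin_MOhm = Rin_MOhm, tau_m_ms = tau_m_ms, rest_mV = rest_mV,
            Ra_MOhm = Ra_MOhm, rheobase_pA = rheobase_pA,
            gain_hz_per_pA = gain_hz_per_pA, adapt_rho = adapt_rho,
            VT_mV = VT_mV, peak_mV = peak_mV,
            rise_slope_mV_per_ms = rise_slope_mV_per_ms,
            fall_slope_mV_per_ms = fall_slope_mV_per_ms,
            ahp_depth_mV = ahp_depth_mV, ahp_recover_ms = ahp_recover_ms,
            noise_sd_mV = noise_sd_mV)
  validate_neuron_params(p)
  class(p) <- "neuron_params"
  p
}

validate_neuron_params <- function(p) {
  if (!(p$peak_mV > 0))
    stop("`peak_mV` must be above 0 mV")
  if (!(p$VT_mV < 0))
    stop("`VT_mV` must be below 0 mV (spikes must cross 0 mV upward)")
  if (p$rise_slope_mV_per_ms <= 0 || p$fall_slope_mV_per_ms <= 0)
    stop("slopes must be positive")
  if (p$ahp_depth_mV < 0) stop("`ahp_depth_mV` must be >= 0")
  if (p$adapt_rho < 1) stop("`adapt_rho` must be >= 1")
  if (p$Rin_MOhm <= 0 || p$tau_m_ms <= 0)
    stop("passive parameters must be positive")
  if (p$noise_sd_mV < 0) stop("`noise_sd_mV` must be >= 0")
  invisible(p)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat(sprintf(
    paste0("Synthetic neuron: Rin %g MOhm, tau %g ms, rest %g mV, rheobase ",
           "%g pA\n  VT %g mV, peak %g mV, slopes %g/%g mV/ms, AHP %g mV, ",
           "gain %g Hz/pA, rho %g\n"),
    x$Rin_MOhm, x$tau_m_ms, x$rest_mV, x$rheobase_pA, x$VT_mV, x$peak_mV,
    x$rise_slope_mV_per_ms, x$fall_slope_mV_per_ms, x$ahp_depth_mV,
    x$gain_hz_per_pA, x$adapt_rho))
  invisible(x)
}
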