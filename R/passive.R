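#' Passive membrane properties from the -50 pA step
#'
#' Input resistance is taken from the steady-state voltage reached during the
#' -50 pA current injection: `Rin = |dV_ss| / 50 pA`, where `dV_ss` is the
#' mean over the last 20% of the step window minus the pre-step baseline
#' mean. The resting potential is estimated as the pre-step baseline of the
#' sweep whose amplitude is nearest 0 pA.
#'
#' @param sweeps A `sweep_set`.
#' @return An object of class `passive_properties`: list with `resting_mV`,
#'   `input_resistance_MOhm`, `holding_mV`.
#' @export
passive_properties <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_set"))
  proto <- sweeps$protocol
  amps <- proto$amplitudes_pA
  s50 <- which(amps == -50)
  if (!length(s50))
    stop("protocol has no -50 pA sweep; input resistance is undefined")
  s50 <- s50[1]

  v <- sweeps$voltage[, s50]
  if (nrow(detect_spikes(v, proto$sample_rate_hz)) > 0)
    stop("the -50 pA sweep contains spikes; input resistance is undefined")

  t_ms <- protocol_times_ms(proto)
  pre_idx <- which(t_ms < proto$pre_ms)
  win <- step_window_idx(proto)
  ss_idx <- win[t_ms[win] >= proto$pre_ms + 0.8 * proto$step_ms]

  dV <- mean(v[ss_idx]) - mean(v[pre_idx])
  Rin <- abs(dV) / 50 * 1000  # mV / pA -> GOhm -> MOhm

  s0 <- which.min(abs(amps))
  resting <- mean(sweeps$voltage[pre_idx, s0])

  structure(list(resting_mV = resting, input_resistance_MOhm = Rin,
                 holding_mV = proto$holding_mV),
            class = "passive_properties")
}

#' Quality-control gate for a recorded neuron
#'
#' Recordings are excluded when the access resistance is at or above 20 MOhm
#' or the input resistance exceeds 200 MOhm (the latter restricts analysis to
#' a similarly sized neuronal population). A missing access resistance also
#' excludes the cell.
#'
#' @param Ra_MOhm Access resistance, MOhm (NA if unmeasured).
#' @param passive A [passive_properties()] object.
#' @param ra_limit_MOhm Exclusion bound on access resistance (exclude at or
#'   above), MOhm.
#' @param rin_limit_MOhm Exclusion bound on input resistance (exclude above),
#'   MOhm.
#' @return List with `include` (logical) and `reasons` (character vector,
#'   empty when included).
#' @export
qc_gate <- function(Ra_MOhm, passive, ra_limit_MOhm = 20,
                    rin_limit_MOhm = 200) {
  stopifnot(inherits(passive, "passive_properties"))
  reasons <- character(0)
  if (is.null(Ra_MOhm) || is.na(Ra_MOhm)) {
    reasons <- c(reasons, "unmeasured access resistance")
  } else if (Ra_MOhm >= ra_limit_MOhm) {
    reasons <- c(reasons,
                 sprintf("access resistance %.1f MOhm >= %g MOhm",
                         Ra_MOhm, ra_limit_MOhm))
  }
  if (passive$input_resistance_MOhm > rin_limit_MOhm)
    reasons <- c(reasons,
                 sprintf("input resistance %.1f MOhm > %g MOhm",
                         passive$input_resistance_MOhm, rin_limit_MOhm))
  list(include = length(reasons) == 0, reasons = reasons)
}

#' Choose the analysis sweep from per-amplitude spike counts
#'
#' The waveform-analysis sweep is the current injection 100 pA above the
#' minimal level that elicited spiking (the rheobase); if that injection has
#' fewer than three action potentials, the first current injection with more
#' than three action potentials is used instead.
#'
#' @param counts Named numeric vector: spike count per amplitude; names are
#'   the amplitudes in pA.
#' @return List with `amplitude_pA` (NA when no sweep qualifies),
#'   `rheobase_pA` (NA when the neuron never spiked), and `rule` (one of
#'   "rheobase+100", "fallback>3", "none").
#' @export
select_analysis_sweep <- function(counts) {
  amps <- as.numeric(names(counts))
  if (any(is.na(amps))) stop("`counts` must be named by amplitude (pA)")
  o <- order(amps)
  amps <- amps[o]; counts <- as.numeric(counts)[o]

  spiking <- which(counts >= 1)
  if (!length(spiking))
    return(list(amplitude_pA = NA_real_, rheobase_pA = NA_real_,
                rule = "none"))
  rheobase <- amps[spiking[1]]
  cand <- rheobase + 100
  ci <- which(amps == cand)
  if (length(ci) && counts[ci] >= 3)
    return(list(amplitude_pA = cand, rheobase_pA = rheobase,
                rule = "rheobase+100"))
  fb <- which(counts > 3)
  if (length(fb))
    return(list(amplitude_pA = amps[fb[1]], rheobase_pA = rheobase,
                rule = "fallback>3"))
  list(amplitude_pA = NA_real_, rheobase_pA = rheobase, rule = "none")
}
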