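#' Simulate a neuron's current-clamp step responses with known ground truth
#'
#' Renders one voltage sweep per protocol amplitude. Subthreshold sweeps follow
#' the RC charging curve `rest + Rin*I*(1 - exp(-t/tau))`; for amplitudes at or
#' above rheobase, spikes are planted at times giving a first instantaneous
#' frequency `f1(I) = gain * (I - rheobase)` with interspike intervals growing
#' by `adapt_rho` per interval, and each spike is drawn as a piecewise-linear
#' template (rise at `Sr` from threshold to peak, fall at `Sf` to the AHP
#' minimum, then linear relaxation back to threshold). All template
#' breakpoints are snapped to the sample grid so the planted feature values
#' are exact at the recorded resolution; the returned truth table carries the
#' effective (post-snap) slopes and the closed-form half width
#' `(A/2) * (1/Sr + 1/Sf)`.
#'
#' @param params A [neuron_params()] object.
#' @param protocol A [make_step_protocol()] object.
#' @param seed Optional integer seed for the additive noise.
#' @param id Neuron identifier stored in the metadata.
#' @param condition Optional condition label(s) stored in the metadata.
#' @param first_spike_latency_ms Latency of the first planted spike after step
#'   onset, ms.
#'
#' @return An object of class `sweep_set`: list with `voltage` (samples x
#'   sweeps matrix, mV), `protocol`, `meta` (id, condition, `Ra_MOhm`), and
#'   `truth` (planted spike table, per-sweep `f1` values, template constants,
#'   and the generating parameters).
#' @export
simulate_neuron_sweeps <- function(params, protocol, seed = NULL,
                                   id = "neuron-1", condition = NA_character_,
                                   first_spike_latency_ms = 5) {
  stopifnot(inherits(params, "neuron_params"),
            inherits(protocol, "step_protocol"))
  validate_neuron_params(params)
  if (!is.null(seed)) set.seed(seed)

  dt <- protocol$dt_ms
  t_ms <- protocol_times_ms(protocol)
  step_on <- protocol$pre_ms
  step_off <- protocol$pre_ms + protocol$step_ms
  tmpl <- spike_template(params, dt)

  n_sweep <- length(protocol$amplitudes_pA)
  volt <- matrix(NA_real_, nrow = protocol$n_samples, ncol = n_sweep)
  truth_rows <- vector("list", n_sweep)
  f1_planted <- rep(NA_real_, n_sweep)

  for (s in seq_len(n_sweep)) {
    I <- protocol$amplitudes_pA[s]
    if (I >= params$rheobase_pA) {
      onsets <- planted_onsets(params, protocol, I, tmpl,
                               first_spike_latency_ms)
      f1_planted[s] <- params$gain_hz_per_pA * (I - params$rheobase_pA)
      volt[, s] <- render_spiking_sweep(params, protocol, t_ms, onsets, tmpl)
      if (length(onsets)) {
        truth_rows[[s]] <- data.frame(
          sweep = s, amplitude_pA = I, spike = seq_along(onsets),
          onset_ms = onsets,
          cross_ms = onsets + (0 - params$VT_mV) / tmpl$Sr_eff,
          peak_ms = onsets + tmpl$rise_ms,
          ahp_min_ms = onsets + tmpl$rise_ms + tmpl$fall_ms,
          threshold_mV = params$VT_mV,
          amplitude_mV = tmpl$A,
          ahp_depth_mV = params$ahp_depth_mV,
          rise_slope = tmpl$Sr_eff, fall_slope = tmpl$Sf_eff,
          half_width_ms = tmpl$HW_eff)
      }
    } else {
      volt[, s] <- render_subthreshold_sweep(params, t_ms, step_on, step_off, I)
    }
  }
  if (params$noise_sd_mV > 0)
    volt <- volt + stats::rnorm(length(volt), sd = params$noise_sd_mV)

  structure(list(
    voltage = volt,
    protocol = protocol,
    meta = list(id = id, condition = condition, Ra_MOhm = params$Ra_MOhm),
    truth = list(spikes = do.call(rbind, truth_rows),
                 f1_hz = f1_planted,
                 template = tmpl,
                 params = params)
  ), class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  ns <- if (is.null(x$truth$spikes)) 0L else nrow(x$truth$spikes)
  cat(sprintf("Sweep set '%s': %d sweeps x %d samples (%d planted spikes)\n",
              x$meta$id, ncol(x$voltage), nrow(x$voltage), ns))
  invisible(x)
}

# Snap the spike template to the sample grid. Effective slopes differ from the
# requested ones only by the rounding of the rise/fall durations to whole
# samples.
spike_template <- function(params, dt_ms) {
  A <- params$peak_mV - params$VT_mV
  drop <- A + params$ahp_depth_mV
  n_rise <- max(1L, round(A / params$rise_slope_mV_per_ms / dt_ms))
  n_fall <- max(1L, round(drop / params$fall_slope_mV_per_ms / dt_ms))
  rise_ms <- n_rise * dt_ms
  fall_ms <- n_fall * dt_ms
  Sr_eff <- A / rise_ms
  Sf_eff <- drop / fall_ms
  list(A = A, rise_ms = rise_ms, fall_ms = fall_ms,
       Sr_eff = Sr_eff, Sf_eff = Sf_eff,
       HW_eff = (A / 2) * (1 / Sr_eff + 1 / Sf_eff))
}

# Grid-snapped spike onset times (ms) for a suprathreshold amplitude.
planted_onsets <- function(params, protocol, I, tmpl, first_latency_ms) {
  dt <- protocol$dt_ms
  step_off <- protocol$pre_ms + protocol$step_ms
  snap <- function(t) round(t / dt) * dt
  t1 <- snap(protocol$pre_ms + first_latency_ms)
  width <- tmpl$rise_ms + tmpl$fall_ms
  if (t1 + width > step_off)
    stop(sprintf("spike template does not fit the step window at %g pA", I))
  f1 <- params$gain_hz_per_pA * (I - params$rheobase_pA)
  onsets <- t1
  if (f1 > 0) {
    isi <- 1000 / f1
    t_next <- t1
    k <- 0
    repeat {
      t_next <- snap(t_next + isi * params$adapt_rho^k)
      if (t_next + width > step_off) break
      if (t_next - onsets[length(onsets)] <= width)
        stop(sprintf(
          "spike template (%.3f ms) does not fit the ISI at %g pA", width, I))
      onsets <- c(onsets, t_next)
      k <- k + 1
    }
  }
  onsets
}

# Piecewise-linear suprathreshold sweep: baseline at rest, linear approach to
# threshold before the first spike, spike templates with AHP relaxation back
# to threshold between spikes, exponential return to rest after the step.
render_spiking_sweep <- function(params, protocol, t_ms, onsets, tmpl) {
  step_on <- protocol$pre_ms
  step_off <- protocol$pre_ms + protocol$step_ms
  VT <- params$VT_mV
  rest <- params$rest_mV

  kt <- c(0, step_on, onsets[1])
  kv <- c(rest, rest, VT)
  n <- length(onsets)
  for (k in seq_len(n)) {
    o <- onsets[k]
    fall_end <- o + tmpl$rise_ms + tmpl$fall_ms
    bound <- if (k < n) onsets[k + 1] else step_off
    # relaxation always returns fully to threshold; it is compressed when the
    # next onset (or the step end) arrives before `ahp_recover_ms` has passed,
    # so every spike rises from exactly VT
    rec_end <- min(fall_end + params$ahp_recover_ms, bound)
    kt <- c(kt, o + tmpl$rise_ms, fall_end)
    kv <- c(kv, params$peak_mV, VT - params$ahp_depth_mV)
    if (rec_end > fall_end) {
      kt <- c(kt, rec_end)
      kv <- c(kv, VT)
    }
    if (k < n && rec_end < onsets[k + 1]) {
      kt <- c(kt, onsets[k + 1])
      kv <- c(kv, VT)
    }
  }
  if (kt[length(kt)] < step_off) {
    kt <- c(kt, step_off)
    kv <- c(kv, VT)
  }
  keep <- !duplicated(kt)
  kt <- kt[keep]; kv <- kv[keep]

  v <- numeric(length(t_ms))
  in_step <- t_ms < step_off
  v[in_step] <- stats::approx(kt, kv, xout = t_ms[in_step], rule = 2)$y
  v_end <- stats::approx(kt, kv, xout = step_off, rule = 2)$y
  post <- !in_step
  v[post] <- rest + (v_end - rest) *
    exp(-(t_ms[post] - step_off) / params$tau_m_ms)
  v
}

render_subthreshold_sweep <- function(params, t_ms, step_on, step_off, I) {
  rest <- params$rest_mV
  dV <- params$Rin_MOhm * I / 1000  # MOhm * pA -> mV
  v <- rep(rest, length(t_ms))
  during <- t_ms >= step_on & t_ms < step_off
  v[during] <- rest + dV * (1 - exp(-(t_ms[during] - step_on) / params$tau_m_ms))
  v_end <- rest + dV * (1 - exp(-(step_off - step_on) / params$tau_m_ms))
  post <- t_ms >= step_off
  v[post] <- rest + (v_end - rest) * exp(-(t_ms[post] - step_off) / params$tau_m_ms)
  v
}
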