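#' Build a current-step stimulus protocol
#'
#' Describes a family of square current injections delivered from a holding
#' potential: a pre-step baseline, the step itself, and a post-step tail, at a
#' fixed sampling rate. The default arguments reproduce the standard
#' layer-V characterization protocol: 250 ms steps from -250 to 700 pA in
#' 50 pA increments sampled at 20 kHz from ~-65 mV.
#'
#' @param start_pA First (most hyperpolarizing) step amplitude in pA.
#' @param stop_pA Last step amplitude in pA; the amplitude list runs from
#'   `start_pA` upward in `increment_pA` steps without exceeding `stop_pA`.
#' @param increment_pA Step increment in pA; must be positive.
#' @param pre_ms Baseline duration before the step, ms.
#' @param step_ms Step duration, ms.
#' @param post_ms Duration recorded after the step, ms.
#' @param sample_rate_hz Sampling rate in samples per second.
#' @param holding_mV Commanded baseline potential, mV.
#'
#' @return An object of class `step_protocol`: a list with fields
#'   `pre_ms`, `step_ms`, `post_ms`, `amplitudes_pA`, `sample_rate_hz`,
#'   `holding_mV`, plus derived `dt_ms` and `n_samples`.
#' @export
#' @examples
#' p <- make_step_protocol()
#' length(p$amplitudes_pA)   # 20 amplitudes
make_step_protocol <- function(start_pA = -250, stop_pA = 700,
                               increment_pA = 50,
                               pre_ms = 100, step_ms = 250, post_ms = 150,
                               sample_rate_hz = 20000, holding_mV = -65) {
  if (!is.numeric(increment_pA) || increment_pA <= 0)
    stop("`increment_pA` must be positive")
  if (stop_pA < start_pA) stop("`stop_pA` must be >= `start_pA`")
  if (sample_rate_hz <= 0) stop("`sample_rate_hz` must be positive")
  if (step_ms <= 0) stop("`step_ms` must be positive")
  amplitudes <- seq(start_pA, stop_pA, by = increment_pA)
  total_ms <- pre_ms + step_ms + post_ms
  proto <- list(
    pre_ms = pre_ms, step_ms = step_ms, post_ms = post_ms,
    amplitudes_pA = amplitudes,
    sample_rate_hz = sample_rate_hz,
    holding_mV = holding_mV,
    dt_ms = 1000 / sample_rate_hz,
    n_samples = round(total_ms * sample_rate_hz / 1000)
  )
  class(proto) <- "step_protocol"
  proto
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf(
    "Step protocol: %d amplitudes %g..%g pA, %g ms step (%g ms pre, %g ms post), %g kHz\n",
    length(x$amplitudes_pA), min(x$amplitudes_pA), max(x$amplitudes_pA),
    x$step_ms, x$pre_ms, x$post_ms, x$sample_rate_hz / 1000))
  invisible(x)
}

# Sample times (ms, t = 0 at first sample) for a protocol.
protocol_times_ms <- function(protocol) {
  (seq_len(protocol$n_samples) - 1) * protocol$dt_ms
}

# Index range of the step window [pre, pre + step) on the sample grid.
step_window_idx <- function(protocol) {
  t <- protocol_times_ms(protocol)
  which(t >= protocol$pre_ms & t < protocol$pre_ms + protocol$step_ms)
}
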