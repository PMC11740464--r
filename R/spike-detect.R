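#' Detect action potentials as upward 0 mV crossings
#'
#' Spike timing follows the standard event definition for current-clamp data:
#' an event is recorded where the membrane potential crosses 0 mV with
#' positive slope. Crossing times are linearly interpolated between the two
#' bracketing samples, a 1 ms dead time suppresses re-triggering, and each
#' event's peak is the maximum voltage between the upward crossing and the
#' next downward 0 mV crossing (or the end of the trace).
#'
#' @param voltage_mV Numeric vector, uniformly sampled membrane potential.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param dead_time_ms Minimum separation between events, ms.
#'
#' @return A data.frame of class `spike_train` with columns `time_ms`
#'   (interpolated 0 mV crossing), `peak_time_ms`, `peak_mV`, and the sample
#'   indices `cross_idx`, `peak_idx`. Zero rows when no spike is present.
#' @export
detect_spikes <- function(voltage_mV, sample_rate_hz, dead_time_ms = 1) {
  v <- as.numeric(voltage_mV)
  dt <- 1000 / sample_rate_hz
  n <- length(v)
  empty <- structure(
    list(time_ms = numeric(0), peak_time_ms = numeric(0),
         peak_mV = numeric(0), cross_idx = integer(0),
         peak_idx = integer(0)),
    class = c("spike_train", "data.frame"), row.names = integer(0))
  if (n < 2 || max(v) < 0) return(empty)

  nonneg <- v >= 0
  flip <- which(nonneg[-1] != nonneg[-n])
  up <- flip[!nonneg[flip]]
  down <- flip[nonneg[flip]]
  if (!length(up)) return(empty)

  # 1 ms dead time after each accepted event
  t_up <- (up - 1) * dt + dt * (0 - v[up]) / (v[up + 1] - v[up])
  keep <- logical(length(up))
  last_t <- -Inf
  for (i in seq_along(up)) {
    if (t_up[i] - last_t >= dead_time_ms) {
      keep[i] <- TRUE
      last_t <- t_up[i]
    }
  }
  up <- up[keep]; t_up <- t_up[keep]

  peak_idx <- integer(length(up))
  for (i in seq_along(up)) {
    end_i <- down[down >= up[i]]
    end_i <- if (length(end_i)) end_i[1] else n
    seg <- (up[i] + 1):min(end_i, n)
    peak_idx[i] <- seg[which.max(v[seg])]
  }
  structure(
    list(time_ms = t_up, peak_time_ms = (peak_idx - 1) * dt,
         peak_mV = v[peak_idx], cross_idx = up, peak_idx = peak_idx),
    class = c("spike_train", "data.frame"),
    row.names = seq_along(up))
}
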