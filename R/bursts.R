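#' Detect polysynaptic bursts in a continuous current-clamp trace
#'
#' A burst is a compound depolarization exceeding the printed amplitude
#' criterion (> 2 mV above baseline). The baseline is the median of the first
#' `baseline_s` seconds (robust to slow drift), the trace is smoothed with a
#' `smooth_s` moving average, candidate regions are contiguous samples whose
#' smoothed depolarization exceeds the threshold, regions closer than
#' `merge_gap_s` are merged, and regions shorter than `min_dur_s` are
#' dropped. The onset is the first sample of each surviving region. The
#' detector never reads condition labels.
#'
#' @param trace Numeric vector, membrane potential in mV.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param amp_threshold_mV Amplitude criterion above baseline, mV.
#' @param merge_gap_s Regions closer than this are one burst, s.
#' @param min_dur_s Minimum region duration, s.
#' @param smooth_s Moving-average window, s.
#' @param baseline_s Baseline-estimation window at the trace start, s.
#' @return Data.frame of class `burst_events` with `onset_s`, `peak_amp_mV`
#'   (relative to baseline), `duration_s`; attributes `baseline_mV` and
#'   `threshold_mV`.
#' @export
detect_bursts <- function(trace, sample_rate_hz, amp_threshold_mV = 2,
                          merge_gap_s = 0.2, min_dur_s = 0.05,
                          smooth_s = 0.05, baseline_s = 10) {
  fs <- sample_rate_hz
  n <- length(trace)
  if (n < baseline_s * fs)
    stop(sprintf("trace shorter than the %g s baseline window", baseline_s))
  baseline <- stats::median(trace[seq_len(round(baseline_s * fs))])

  w <- max(1, round(smooth_s * fs))
  sm <- moving_average(trace, w)
  above <- (sm - baseline) > amp_threshold_mV

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  reg <- cbind(starts[r$values], ends[r$values])
  if (!is.null(dim(reg)) && nrow(reg) > 1) {
    gap <- round(merge_gap_s * fs)
    merged <- reg[1, , drop = FALSE]
    for (i in 2:nrow(reg)) {
      if (reg[i, 1] - merged[nrow(merged), 2] <= gap) {
        merged[nrow(merged), 2] <- reg[i, 2]
      } else merged <- rbind(merged, reg[i, ])
    }
    reg <- merged
  }
  out <- data.frame(onset_s = numeric(0), peak_amp_mV = numeric(0),
                    duration_s = numeric(0))
  if (length(reg)) {
    dur <- (reg[, 2] - reg[, 1] + 1) / fs
    keep <- dur >= min_dur_s
    reg <- reg[keep, , drop = FALSE]
    if (nrow(reg)) {
      peak <- vapply(seq_len(nrow(reg)), function(i)
        max(trace[reg[i, 1]:reg[i, 2]]) - baseline, numeric(1))
      out <- data.frame(onset_s = (reg[, 1] - 1) / fs,
                        peak_amp_mV = peak,
                        duration_s = (reg[, 2] - reg[, 1] + 1) / fs)
    }
  }
  attr(out, "baseline_mV") <- baseline
  attr(out, "threshold_mV") <- amp_threshold_mV
  class(out) <- c("burst_events", "data.frame")
  out
}

moving_average <- function(x, w) {
  if (w <= 1) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2
  lo <- pmax(0, seq_len(n) - half - 1)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

#' Latency to the second recurrent polysynaptic burst
#'
#' The network-hyperexcitability statistic: time from the trace start (taken
#' to coincide with solution application) to the onset of the second clearly
#' recurrent burst. Missing when fewer than two bursts were detected.
#'
#' @param events A `burst_events` data.frame from [detect_bursts()].
#' @return List of class `network_latency` with `latency_s` (NA when
#'   `n_bursts < 2`), `n_bursts`, `baseline_mV`, `threshold_mV`.
#' @export
latency_to_second_burst <- function(events) {
  stopifnot(inherits(events, "burst_events"))
  structure(list(
    latency_s = if (nrow(events) >= 2) events$onset_s[2] else NA_real_,
    n_bursts = nrow(events),
    baseline_mV = attr(events, "baseline_mV"),
    threshold_mV = attr(events, "threshold_mV")),
    class = "network_latency")
}

#' @export
print.network_latency <- function(x, ...) {
  cat(sprintf("Bursts: %d; latency to second burst: %s s\n", x$n_bursts,
              if (is.na(x$latency_s)) "NA" else sprintf("%.2f", x$latency_s)))
  invisible(x)
}
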