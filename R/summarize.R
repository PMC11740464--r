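#' Full per-neuron analysis of a step-protocol sweep set
#'
#' Runs the intracellular pipeline in order: passive properties, QC gate,
#' spike detection on every sweep, analysis-sweep selection (rheobase +
#' 100 pA with the >3-AP fallback), per-spike waveform features averaged over
#' the analysis sweep, adaptation index, and the F-I curve. Neurons that fail
#' QC stop after the gate and carry flags but no downstream statistics.
#' Component failures are recorded as flags; the function never aborts a
#' batch.
#'
#' @param sweeps A `sweep_set`.
#' @param window_ms,smooth_ms Passed to [ap_waveform_features()].
#' @param exclude_last_ahp If TRUE, the final spike's AHP (measured to the
#'   end of the step rather than to a following spike) is excluded from the
#'   per-sweep AHP mean.
#' @return An object of class `neuron_summary`.
#' @export
summarize_neuron <- function(sweeps, window_ms = 3, smooth_ms = 0.35,
                             exclude_last_ahp = FALSE) {
  stopifnot(inherits(sweeps, "sweep_set"))
  proto <- sweeps$protocol
  out <- list(id = sweeps$meta$id, condition = sweeps$meta$condition,
              Ra_MOhm = sweeps$meta$Ra_MOhm, flags = character(0),
              included = FALSE)
  class(out) <- "neuron_summary"

  passive <- tryCatch(passive_properties(sweeps), error = function(e) e)
  if (inherits(passive, "error")) {
    out$flags <- c(out$flags, conditionMessage(passive))
    return(out)
  }
  out$resting_mV <- passive$resting_mV
  out$input_resistance_MOhm <- passive$input_resistance_MOhm

  gate <- qc_gate(sweeps$meta$Ra_MOhm, passive)
  out$included <- gate$include
  out$flags <- c(out$flags, gate$reasons)
  if (!gate$include) return(out)

  trains <- lapply(seq_len(ncol(sweeps$voltage)), function(s)
    detect_spikes(sweeps$voltage[, s], proto$sample_rate_hz))
  counts <- vapply(trains, nrow, integer(1))
  names(counts) <- proto$amplitudes_pA
  out$fi <- fi_curve(trains, proto$amplitudes_pA)

  sel <- select_analysis_sweep(counts)
  out$rheobase_pA <- sel$rheobase_pA
  out$analysis_amplitude_pA <- sel$amplitude_pA
  out$selection_rule <- sel$rule
  if (is.na(sel$amplitude_pA)) {
    out$flags <- c(out$flags, "no analysis sweep qualified")
    return(out)
  }

  s <- which(proto$amplitudes_pA == sel$amplitude_pA)[1]
  feats <- tryCatch(
    ap_waveform_features(sweeps$voltage[, s], proto$sample_rate_hz,
                         trains[[s]],
                         step_end_ms = proto$pre_ms + proto$step_ms,
                         window_ms = window_ms, smooth_ms = smooth_ms),
    error = function(e) e)
  if (inherits(feats, "error")) {
    out$flags <- c(out$flags, conditionMessage(feats))
    return(out)
  }
  out$ap_features <- feats
  ok <- feats[feats$ok, , drop = FALSE]
  if (nrow(ok)) {
    ahp_vals <- ok$ahp_mV
    if (exclude_last_ahp && nrow(ok) > 1 &&
        ok$spike[nrow(ok)] == nrow(feats))
      ahp_vals <- ahp_vals[-length(ahp_vals)]
    out$threshold_mV <- mean(ok$threshold_mV)
    out$amplitude_mV <- mean(ok$amplitude_mV)
    out$half_width_ms <- mean(ok$half_width_ms, na.rm = TRUE)
    out$ahp_mV <- mean(ahp_vals)
    out$rise_slope_mV_per_ms <- mean(ok$rise_slope_mV_per_ms)
    out$fall_slope_mV_per_ms <- mean(ok$fall_slope_mV_per_ms)
  }
  if (sum(!feats$ok))
    out$flags <- c(out$flags, sprintf("%d edge spike(s) without features",
                                      sum(!feats$ok)))
  out$adaptation_index <- adaptation_index(trains[[s]]$time_ms)
  out
}

#' @export
print.neuron_summary <- function(x, ...) {
  cat(sprintf("Neuron '%s' (%s): %s\n", x$id,
              paste(x$condition, collapse = "/"),
              if (x$included) "included" else
                paste("excluded:", paste(x$flags, collapse = "; "))))
  if (x$included && !is.null(x$threshold_mV))
    cat(sprintf(
      "  VT %.2f mV, amp %.1f mV, HW %.3f ms, AHP %.2f mV, adapt %.2f\n",
      x$threshold_mV, x$amplitude_mV, x$half_width_ms, x$ahp_mV,
      x$adaptation_index))
  invisible(x)
}

#' Summarize a batch of neurons into one row per neuron
#'
#' @param sweep_sets List of `sweep_set` objects.
#' @param ... Passed to [summarize_neuron()].
#' @return List with `summaries` (per-neuron `neuron_summary` objects, input
#'   order preserved) and `table` (one row per neuron).
#' @export
summarize_cohort <- function(sweep_sets, ...) {
  summaries <- lapply(sweep_sets, summarize_neuron, ...)
  list(summaries = summaries,
       table = do.call(rbind, lapply(summaries, neuron_summary_row)))
}

# One-row data.frame form of a neuron_summary (NA for absent fields).
neuron_summary_row <- function(x) {
  g <- function(f) if (is.null(x[[f]])) NA_real_ else x[[f]]
  data.frame(
    id = x$id, condition = paste(x$condition, collapse = "/"),
    included = x$included,
    flags = paste(x$flags, collapse = "; "),
    Ra_MOhm = g("Ra_MOhm"),
    resting_mV = g("resting_mV"),
    input_resistance_MOhm = g("input_resistance_MOhm"),
    rheobase_pA = g("rheobase_pA"),
    analysis_amplitude_pA = g("analysis_amplitude_pA"),
    threshold_mV = g("threshold_mV"),
    amplitude_mV = g("amplitude_mV"),
    half_width_ms = g("half_width_ms"),
    ahp_mV = g("ahp_mV"),
    rise_slope_mV_per_ms = g("rise_slope_mV_per_ms"),
    fall_slope_mV_per_ms = g("fall_slope_mV_per_ms"),
    adaptation_index = g("adaptation_index"))
}

#' AP-count and F-I matrices for a cohort (neurons x amplitudes)
#'
#' Convenience accessor used by the repeated-measures analyses: collects the
#' per-neuron F-I tables of included neurons into matrices over the shared
#' amplitude grid.
#'
#' @param cohort Result of [summarize_cohort()].
#' @param amplitudes_pA Amplitudes to keep (default: all depolarizing).
#' @return List with `counts`, `f1` (matrices with neuron ids as rownames)
#'   and `condition` (per kept neuron).
#' @export
cohort_fi_matrices <- function(cohort, amplitudes_pA = NULL) {
  keep <- vapply(cohort$summaries, function(s)
    isTRUE(s$included) && !is.null(s$fi), logical(1))
  ss <- cohort$summaries[keep]
  if (!length(ss)) stop("no included neurons with F-I data")
  amps <- ss[[1]]$fi$amplitude_pA
  if (is.null(amplitudes_pA)) amplitudes_pA <- amps[amps > 0]
  ai <- match(amplitudes_pA, amps)
  if (any(is.na(ai))) stop("requested amplitudes missing from the F-I grid")
  counts <- t(vapply(ss, function(s) s$fi$n_spikes[ai],
                     numeric(length(ai))))
  f1 <- t(vapply(ss, function(s) s$fi$f1_hz[ai], numeric(length(ai))))
  rownames(counts) <- rownames(f1) <-
    vapply(ss, function(s) s$id, character(1))
  colnames(counts) <- colnames(f1) <- amplitudes_pA
  list(counts = counts, f1 = f1,
       condition = vapply(ss, function(s)
         paste(s$condition, collapse = "/"), character(1)))
}
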