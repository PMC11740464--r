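#' Write a sweep archive (one directory per neuron)
#'
#' Interchange format for step-protocol recordings: per neuron a directory
#' holding `meta.json` (protocol, access resistance, condition, id) and
#' `sweeps.csv` with columns `sweep_index`, `time_ms`, `voltage_mV`.
#'
#' @param sweep_sets List of `sweep_set` objects (or a single one).
#' @param dir Target directory (created if needed).
#' @return Invisibly, the per-neuron directories written.
#' @export
write_sweep_archive <- function(sweep_sets, dir) {
  if (inherits(sweep_sets, "sweep_set")) sweep_sets <- list(sweep_sets)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (ss in sweep_sets) {
    nd <- file.path(dir, ss$meta$id)
    dir.create(nd, showWarnings = FALSE)
    proto <- ss$protocol
    meta <- list(id = ss$meta$id, condition = ss$meta$condition,
                 Ra_MOhm = ss$meta$Ra_MOhm,
                 protocol = proto[c("pre_ms", "step_ms", "post_ms",
                                    "amplitudes_pA", "sample_rate_hz",
                                    "holding_mV")])
    jsonlite::write_json(meta, file.path(nd, "meta.json"),
                         auto_unbox = TRUE, digits = NA)
    t_ms <- protocol_times_ms(proto)
    long <- data.frame(
      sweep_index = rep(seq_len(ncol(ss$voltage)), each = nrow(ss$voltage)),
      time_ms = rep(t_ms, times = ncol(ss$voltage)),
      voltage_mV = as.vector(ss$voltage))
    utils::write.csv(long, file.path(nd, "sweeps.csv"), row.names = FALSE)
    written <- c(written, nd)
  }
  invisible(written)
}

#' Read a sweep archive written by [write_sweep_archive()]
#'
#' @param dir Archive directory (containing per-neuron subdirectories).
#' @return List of `sweep_set` objects (without truth tables).
#' @export
read_sweep_archive <- function(dir) {
  sub <- list.dirs(dir, recursive = FALSE)
  if (!length(sub)) stop("no neuron directories found in archive")
  lapply(sub, function(nd) {
    meta <- jsonlite::read_json(file.path(nd, "meta.json"),
                                simplifyVector = TRUE)
    p <- meta$protocol
    proto <- structure(list(
      pre_ms = p$pre_ms, step_ms = p$step_ms, post_ms = p$post_ms,
      amplitudes_pA = as.numeric(p$amplitudes_pA),
      sample_rate_hz = p$sample_rate_hz, holding_mV = p$holding_mV,
      dt_ms = 1000 / p$sample_rate_hz,
      n_samples = round((p$pre_ms + p$step_ms + p$post_ms) *
                          p$sample_rate_hz / 1000)),
      class = "step_protocol")
    long <- utils::read.csv(file.path(nd, "sweeps.csv"))
    volt <- matrix(long$voltage_mV, nrow = proto$n_samples)
    structure(list(voltage = volt, protocol = proto,
                   meta = list(id = meta$id, condition = meta$condition,
                               Ra_MOhm = meta$Ra_MOhm),
                   truth = NULL),
              class = "sweep_set")
  })
}

#' Write a rendered stack as multi-page TIFF plus a scene sidecar
#'
#' Pages are ordered channel-major (all z of channel 1, then channel 2, ...),
#' i.e. CZYX; the layout, channel names, voxel size, intensity scale and
#' offset, and the scene truth are recorded in `scene.json` next to the TIFF.
#'
#' @param stack An `mg_stack`.
#' @param tiff_path Output TIFF path; the sidecar is written as `scene.json`
#'   in the same directory.
#' @return Invisibly, `tiff_path`.
#' @export
write_stack_tiff <- function(stack, tiff_path) {
  stopifnot(inherits(stack, "mg_stack"))
  # TIFF pages must lie in [0, 1]; noise can push voxels negative, so map
  # [offset, offset + scale] -> [0, 1] and record both in the sidecar.
  offset <- min(0, vapply(stack$channels, min, numeric(1)))
  scale <- max(vapply(stack$channels, max, numeric(1)) - offset, 1)
  pages <- list()
  for (ch in stack$channels) {
    for (z in seq_len(dim(ch)[1]))
      pages[[length(pages) + 1]] <- (ch[z, , ] - offset) / scale
  }
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L)
  sidecar <- list(layout = "CZYX",
                  channel_names = names(stack$channels),
                  shape_vox = dim(stack$channels[[1]]),
                  voxel_um = stack$voxel_um,
                  intensity_scale = scale,
                  intensity_offset = offset,
                  truth = list(neurons = stack$truth$neurons,
                               microglia = stack$truth$microglia,
                               filaments = lapply(stack$truth$filaments,
                                                  function(fl)
                                                    lapply(fl, as.data.frame))))
  jsonlite::write_json(sidecar,
                       file.path(dirname(tiff_path), "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(tiff_path)
}

#' Read a stack written by [write_stack_tiff()]
#'
#' @param tiff_path TIFF path with its `scene.json` sidecar alongside.
#' @return An `mg_stack` (intensities restored to their original scale).
#' @export
read_stack_tiff <- function(tiff_path) {
  sc <- jsonlite::read_json(file.path(dirname(tiff_path), "scene.json"),
                            simplifyVector = TRUE)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  shape <- as.integer(sc$shape_vox)
  nz <- shape[1]
  channels <- list()
  for (ci in seq_along(sc$channel_names)) {
    arr <- array(0, dim = shape)
    off <- if (is.null(sc$intensity_offset)) 0 else sc$intensity_offset
    for (z in seq_len(nz))
      arr[z, , ] <- pages[[(ci - 1) * nz + z]] * sc$intensity_scale + off
    channels[[sc$channel_names[ci]]] <- arr
  }
  filaments <- lapply(sc$truth$filaments, function(fl)
    lapply(fl, function(df) {
      m <- cbind(df$z_um, df$y_um, df$x_um)
      dimnames(m) <- list(NULL, c("z_um", "y_um", "x_um"))
      m
    }))
  structure(list(channels = channels, voxel_um = as.numeric(sc$voxel_um),
                 truth = list(neurons = sc$truth$neurons,
                              microglia = sc$truth$microglia,
                              filaments = filaments, scene = NULL)),
            class = "mg_stack")
}
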