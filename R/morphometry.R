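#' Threshold-based 3D segmentation into labelled objects
#'
#' Voxels above the intensity threshold are grouped into 26-connected
#' components (a deterministic stand-in for interactive surface creation);
#' components smaller than `min_size_um3` are dropped.
#'
#' @param img 3D numeric array (z, y, x).
#' @param voxel_um Physical voxel edges (z, y, x), um.
#' @param intensity_threshold Voxels strictly above this value are foreground.
#' @param min_size_um3 Minimum object volume, um^3.
#' @return An object of class `label_volume`: list with `labels` (integer 3D
#'   array, 0 = background), `voxel_um`, `n_labels`, and `sizes`
#'   (data.frame `label`, `n_vox`, `volume_um3`).
#' @export
segment_stack <- function(img, voxel_um, intensity_threshold,
                          min_size_um3 = 0) {
  if (length(dim(img)) != 3) stop("`img` must be a 3D array")
  shape <- dim(img)
  mask <- img > intensity_threshold
  fg <- which(mask)
  labels <- array(0L, dim = shape)
  if (length(fg)) {
    coords <- arrayInd(fg, shape)
    lookup <- integer(prod(shape))
    lookup[fg] <- seq_along(fg)
    offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    offs <- offs[offs[, 1] + 3 * offs[, 2] + 9 * offs[, 3] > 0, , drop = FALSE]
    edges <- list()
    for (r in seq_len(nrow(offs))) {
      nb <- coords
      nb[, 1] <- nb[, 1] + offs[r, 1]
      nb[, 2] <- nb[, 2] + offs[r, 2]
      nb[, 3] <- nb[, 3] + offs[r, 3]
      ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
        nb[, 2] >= 1 & nb[, 2] <= shape[2] &
        nb[, 3] >= 1 & nb[, 3] <= shape[3]
      nidx <- (nb[ok, 3] - 1) * shape[1] * shape[2] +
        (nb[ok, 2] - 1) * shape[1] + nb[ok, 1]
      hit <- lookup[nidx] > 0
      if (any(hit))
        edges[[r]] <- cbind(lookup[fg[ok]][hit], lookup[nidx][hit])
    }
    g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
    if (length(edges)) {
      em <- do.call(rbind, edges)
      g <- igraph::add_edges(g, as.vector(t(em)))
    }
    memb <- igraph::components(g)$membership
    vol_vox <- prod(voxel_um)
    sizes <- tabulate(memb)
    keep <- which(sizes * vol_vox >= min_size_um3 & sizes > 0)
    relab <- integer(length(sizes))
    relab[keep] <- seq_along(keep)
    labels[fg] <- relab[memb]
  }
  kept_sizes <- tabulate(labels[labels > 0])
  structure(list(labels = labels, voxel_um = voxel_um,
                 n_labels = length(kept_sizes),
                 sizes = data.frame(label = seq_along(kept_sizes),
                                    n_vox = kept_sizes,
                                    volume_um3 = kept_sizes * prod(voxel_um))),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("Label volume: %d objects, grid %s, voxel %s um\n",
              x$n_labels, paste(dim(x$labels), collapse = "x"),
              paste(x$voxel_um, collapse = "x")))
  invisible(x)
}

# Dilate a set of linear voxel indices by `steps` in the given neighbourhood.
dilate_indices <- function(idx, shape, steps = 1,
                           neighbourhood = c("full", "face")) {
  neighbourhood <- match.arg(neighbourhood)
  if (!length(idx) || steps < 1) return(idx)
  cur <- idx
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  if (neighbourhood == "face")
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  else
    offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  for (s in seq_len(steps)) {
    coords <- arrayInd(cur, shape)
    out <- list(cur)
    for (r in seq_len(nrow(offs))) {
      nb <- coords
      nb[, 1] <- nb[, 1] + offs[r, 1]
      nb[, 2] <- nb[, 2] + offs[r, 2]
      nb[, 3] <- nb[, 3] + offs[r, 3]
      ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
        nb[, 2] >= 1 & nb[, 2] <= shape[2] &
        nb[, 3] >= 1 & nb[, 3] <= shape[3]
      out[[r + 1]] <- (nb[ok, 3] - 1) * shape[1] * shape[2] +
        (nb[ok, 2] - 1) * shape[1] + nb[ok, 1]
    }
    cur <- unique(unlist(out))
  }
  cur
}

#' Classify satellite microglia in 3D
#'
#' A microglia counts as the satellite of a neuron only when both printed
#' criteria hold in 3D: its soma is in contact with the neuronal soma AND at
#' least one of its processes touches/wraps the neuronal soma. Contact is
#' quantified as 26-neighbourhood adjacency within `contact_dist_vox` voxels.
#' For satellite pairs, the microglia-neuron volume overlap (with ratios to
#' the microglial and neuronal soma volumes) and the soma contact surface
#' area are reported.
#'
#' @param neuron_labels A `label_volume` of the neuron (soma) channel.
#' @param mg_labels A `label_volume` of the microglia channel (somata +
#'   processes), used for the overlap metrics.
#' @param mg_somata Data.frame with microglia soma geometry: columns `id`,
#'   `z_um`, `y_um`, `x_um`, `radius_um` (scene truth, or an isolated-soma
#'   segmentation).
#' @param filaments Named list (by microglia id) of process polylines
#'   (matrices of zyx points in um).
#' @param contact_dist_vox Adjacency distance in voxels.
#' @param process_radius_um Tube radius used to rasterize filaments.
#' @return List with `calls` (one row per neuron label: `neuron_label`,
#'   `satellite`, `partner_mg`, `soma_contact`, `process_contact`,
#'   `overlap_um3`, `overlap_over_mg`, `overlap_over_neuron`,
#'   `contact_area_um2`) and `percent_satellite` (the per-image percentage of
#'   neurons with a satellite).
#' @export
classify_satellites <- function(neuron_labels, mg_labels, mg_somata,
                                filaments, contact_dist_vox = 1,
                                process_radius_um = 0.6) {
  stopifnot(inherits(neuron_labels, "label_volume"),
            inherits(mg_labels, "label_volume"))
  if (!identical(dim(neuron_labels$labels), dim(mg_labels$labels)))
    stop("neuron and microglia label volumes are on different grids")
  shape <- dim(neuron_labels$labels)
  vox <- neuron_labels$voxel_um
  labs <- neuron_labels$labels
  n_lab <- neuron_labels$n_labels
  if (n_lab == 0)
    return(list(calls = data.frame(), percent_satellite = NA_real_))

  # per-microglia: neuron labels contacted by the soma and by the processes
  soma_hits <- list(); proc_hits <- list(); soma_idx <- list()
  for (j in seq_len(nrow(mg_somata))) {
    id <- mg_somata$id[j]
    s_idx <- sphere_voxels(c(mg_somata$z_um[j], mg_somata$y_um[j],
                             mg_somata$x_um[j]),
                           mg_somata$radius_um[j], shape, vox)
    soma_idx[[id]] <- s_idx
    dil <- dilate_indices(s_idx, shape, steps = contact_dist_vox)
    soma_hits[[id]] <- setdiff(unique(labs[dil]), 0L)
    p_idx <- integer(0)
    for (poly in filaments[[id]])
      p_idx <- c(p_idx, tube_voxels(poly, process_radius_um, shape, vox))
    p_idx <- unique(p_idx)
    dil <- dilate_indices(p_idx, shape, steps = contact_dist_vox)
    proc_hits[[id]] <- setdiff(unique(labs[dil]), 0L)
  }

  mg_ids <- mg_somata$id
  calls <- data.frame(neuron_label = seq_len(n_lab), satellite = FALSE,
                      partner_mg = NA_character_, soma_contact = FALSE,
                      process_contact = FALSE, overlap_um3 = NA_real_,
                      overlap_over_mg = NA_real_,
                      overlap_over_neuron = NA_real_,
                      contact_area_um2 = NA_real_)
  for (lab in seq_len(n_lab)) {
    sc <- vapply(mg_ids, function(id) lab %in% soma_hits[[id]], logical(1))
    pc <- vapply(mg_ids, function(id) lab %in% proc_hits[[id]], logical(1))
    calls$soma_contact[lab] <- any(sc)
    calls$process_contact[lab] <- any(pc)
    both <- which(sc & pc)
    if (length(both)) {
      id <- mg_ids[both[1]]
      calls$satellite[lab] <- TRUE
      calls$partner_mg[lab] <- id
      # overlap against the full microglia object containing this soma
      center_idx <- soma_idx[[id]][1]
      mg_lab <- mg_labels$labels[center_idx]
      if (mg_lab > 0) {
        mg_mask <- mg_labels$labels == mg_lab
        nn_mask <- labs == lab
        ov <- overlap_metrics(mg_mask, nn_mask, vox)
        calls$overlap_um3[lab] <- ov$overlap_um3
        calls$overlap_over_mg[lab] <- ov$ratio_a
        calls$overlap_over_neuron[lab] <- ov$ratio_b
        calls$contact_area_um2[lab] <-
          contact_surface_area(mg_mask, nn_mask, vox)
      }
    }
  }
  list(calls = calls, percent_satellite = 100 * mean(calls$satellite))
}

#' Volume overlap between two 3D objects
#'
#' @param mask_a,mask_b Logical 3D arrays on the same grid.
#' @param voxel_um Voxel edges (z, y, x), um.
#' @return List with `overlap_um3`, `ratio_a` (overlap / volume of a) and
#'   `ratio_b` (overlap / volume of b).
#' @export
overlap_metrics <- function(mask_a, mask_b, voxel_um) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks are on different grids")
  va <- sum(mask_a); vb <- sum(mask_b)
  if (va == 0 || vb == 0) stop("zero-volume object")
  ov <- sum(mask_a & mask_b)
  vol <- prod(voxel_um)
  list(overlap_um3 = ov * vol, ratio_a = ov / va, ratio_b = ov / vb)
}

#' Contact surface area between two 3D objects
#'
#' Sums the areas of voxel faces of object B (the neuron) whose across-face
#' neighbour lies in object A (the microglia), honouring anisotropic voxels:
#' faces normal to z have area `dy*dx`, and so on.
#'
#' @param mask_a,mask_b Logical 3D arrays on the same grid.
#' @param voxel_um Voxel edges (z, y, x), um.
#' @return Contact area in um^2 (0 for disjoint objects).
#' @export
contact_surface_area <- function(mask_a, mask_b, voxel_um) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks are on different grids")
  d <- dim(mask_a)
  face_area <- c(voxel_um[2] * voxel_um[3],  # normal to z
                 voxel_um[1] * voxel_um[3],  # normal to y
                 voxel_um[1] * voxel_um[2])  # normal to x
  total <- 0
  # axis 1 (z)
  total <- total + face_area[1] *
    (sum(mask_b[-d[1], , ] & mask_a[-1, , ]) +
     sum(mask_b[-1, , ] & mask_a[-d[1], , ]))
  # axis 2 (y)
  total <- total + face_area[2] *
    (sum(mask_b[, -d[2], ] & mask_a[, -1, ]) +
     sum(mask_b[, -1, ] & mask_a[, -d[2], ]))
  # axis 3 (x)
  total <- total + face_area[3] *
    (sum(mask_b[, , -d[3]] & mask_a[, , -1]) +
     sum(mask_b[, , -1] & mask_a[, , -d[3]]))
  total
}

#' cfos positivity calls and the satellite-by-cfos summary
#'
#' A neuron is cfos-positive when its mean soma intensity exceeds the
#' background (median of all non-soma voxels) by `k_sd` robust standard
#' deviations (MAD). The 2x2 summary reports the percentage of positive
#' neurons among satellite-associated and non-associated neurons.
#'
#' @param cfos_img 3D numeric array, cfos channel.
#' @param neuron_labels A `label_volume` of neuron somata.
#' @param satellite Logical vector, per neuron label.
#' @param k_sd Positivity threshold in robust SDs above background.
#' @return List with `calls` (per neuron: `neuron_label`, `mean_intensity`,
#'   `background`, `positive`, `satellite`), `background` (med, sd), and
#'   `summary` (percent positive by satellite status).
#' @export
cfos_positivity <- function(cfos_img, neuron_labels, satellite, k_sd = 2) {
  stopifnot(inherits(neuron_labels, "label_volume"))
  if (!identical(dim(cfos_img), dim(neuron_labels$labels)))
    stop("cfos channel and neuron labels are on different grids")
  labs <- neuron_labels$labels
  n_lab <- neuron_labels$n_labels
  if (n_lab == 0)
    return(list(calls = data.frame(), background = NULL, summary = NULL))
  if (length(satellite) != n_lab)
    stop("`satellite` must have one entry per neuron label")
  bg_vox <- cfos_img[labs == 0]
  bg_med <- stats::median(bg_vox)
  bg_sd <- stats::mad(bg_vox)
  means <- vapply(seq_len(n_lab), function(l) mean(cfos_img[labs == l]),
                  numeric(1))
  pos <- means > bg_med + k_sd * bg_sd
  calls <- data.frame(neuron_label = seq_len(n_lab), mean_intensity = means,
                      background = bg_med, positive = pos,
                      satellite = satellite)
  pct <- function(x) if (length(x)) 100 * mean(x) else NA_real_
  list(calls = calls,
       background = list(median = bg_med, sd = bg_sd),
       summary = data.frame(
         group = c("satellite", "non_satellite"),
         n = c(sum(satellite), sum(!satellite)),
         percent_positive = c(pct(pos[satellite]), pct(pos[!satellite]))))
}

#' Percent area of staining within an annotated region
#'
#' 2D grey-matter style quantification: the percentage of annotated pixels
#' whose intensity exceeds the staining threshold.
#'
#' @param img 2D numeric matrix.
#' @param mask Logical matrix, the annotated region.
#' @param threshold Pixels strictly above this value count as stained.
#' @return Percentage in \[0, 100\].
#' @export
percent_area <- function(img, mask, threshold) {
  if (!identical(dim(img), dim(mask))) stop("image and mask differ in shape")
  if (!any(mask)) stop("annotation mask is empty")
  100 * mean(img[mask] > threshold)
}
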