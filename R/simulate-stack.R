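#' Configuration for a synthetic multi-channel 3D image stack
#'
#' Describes a confocal-like z-stack with three channels: branched microglia
#' (GFP-like), neuron somata (Nissl-like), and a cfos channel with planted
#' positives. A chosen fraction of neurons receives a satellite microglia:
#' its soma is placed in direct apposition to the neuron soma (the rendered
#' soma masks touch/interdigitate) and at least one of its processes runs
#' onto the neuronal soma surface. Non-satellite microglia keep a clearance
#' from every neuron and their processes are steered away.
#'
#' @param shape_vox Grid size, voxels, (z, y, x).
#' @param voxel_um Physical voxel edges, micrometers, (z, y, x).
#' @param n_neurons Number of neuron somata.
#' @param soma_radius_um_range Range of neuron soma radii, um.
#' @param n_microglia Number of microglia (must be >= the number of planted
#'   satellites).
#' @param mg_soma_radius_um_range Range of microglia soma radii, um.
#' @param satellite_fraction Target fraction of neurons with a satellite;
#'   `round(satellite_fraction * n_neurons)` satellites are planted.
#' @param processes_per_microglia Processes per microglia.
#' @param process_length_um_range Process length range, um.
#' @param process_radius_um Tube radius of rendered processes, um.
#' @param cfos_fraction Fraction of neurons planted cfos-positive.
#' @param intensity List of channel intensity levels: `background`,
#'   `noise_sd`, `microglia`, `neuron`, `cfos_boost`.
#' @param seed Integer seed.
#' @return An object of class `stack_scene_config`.
#' @export
stack_scene_config <- function(shape_vox = c(24, 160, 160),
                               voxel_um = c(0.5, 0.4, 0.4),
                               n_neurons = 8,
                               soma_radius_um_range = c(3, 4.5),
                               n_microglia = 6,
                               mg_soma_radius_um_range = c(2, 3),
                               satellite_fraction = 0.5,
                               processes_per_microglia = 3,
                               process_length_um_range = c(6, 12),
                               process_radius_um = 0.6,
                               cfos_fraction = 0.4,
                               intensity = list(background = 10, noise_sd = 5,
                                                microglia = 100, neuron = 100,
                                                cfos_boost = 60),
                               seed = 1) {
  if (satellite_fraction < 0 || satellite_fraction > 1)
    stop("`satellite_fraction` must be in [0, 1]")
  if (cfos_fraction < 0 || cfos_fraction > 1)
    stop("`cfos_fraction` must be in [0, 1]")
  n_sat <- round(satellite_fraction * n_neurons)
  if (n_microglia < n_sat)
    stop("`n_microglia` must be at least the number of planted satellites")
  structure(list(shape_vox = shape_vox, voxel_um = voxel_um,
                 n_neurons = n_neurons,
                 soma_radius_um_range = soma_radius_um_range,
                 n_microglia = n_microglia,
                 mg_soma_radius_um_range = mg_soma_radius_um_range,
                 satellite_fraction = satellite_fraction,
                 processes_per_microglia = processes_per_microglia,
                 process_length_um_range = process_length_um_range,
                 process_radius_um = process_radius_um,
                 cfos_fraction = cfos_fraction,
                 intensity = intensity, seed = seed),
            class = "stack_scene_config")
}

#' Render a synthetic 3D stack with scene ground truth
#'
#' @param scene A [stack_scene_config()].
#' @param max_tries Placement retries per object before giving up.
#' @return An object of class `mg_stack`: list with `channels` (named list of
#'   3D arrays `microglia`, `neurons`, `cfos`, indexed (z, y, x)),
#'   `voxel_um`, and `truth` (list: `neurons` and `microglia` data.frames,
#'   `filaments` keyed by microglia id, and the generating `scene`). Physical
#'   positions are 0-based voxel index times voxel size, at voxel centers.
#' @export
render_stack <- function(scene, max_tries = 500) {
  stopifnot(inherits(scene, "stack_scene_config"))
  set.seed(scene$seed)
  shape <- scene$shape_vox
  vox <- scene$voxel_um
  ext <- (shape - 1) * vox  # physical coordinate of the last voxel center

  runif_in <- function(lo, hi) stats::runif(1, lo, hi)
  rand_center <- function(r) {
    margin <- pmin(r + 0.5, ext / 2)
    c(runif_in(margin[1], ext[1] - margin[1]),
      runif_in(margin[2], ext[2] - margin[2]),
      runif_in(margin[3], ext[3] - margin[3]))
  }

  # --- neuron somata: no neuron-neuron overlap -------------------------------
  n_r <- stats::runif(scene$n_neurons, scene$soma_radius_um_range[1],
                      scene$soma_radius_um_range[2])
  n_c <- matrix(NA_real_, scene$n_neurons, 3)
  for (i in seq_len(scene$n_neurons)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- rand_center(n_r[i])
      ok <- TRUE
      if (i > 1) {
        d <- sqrt(colSums((t(n_c[seq_len(i - 1), , drop = FALSE]) - cand)^2))
        ok <- all(d > n_r[seq_len(i - 1)] + n_r[i] + 0.5)
      }
      if (ok) { n_c[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place all neuron somata; use a larger grid")
  }

  n_sat <- round(scene$satellite_fraction * scene$n_neurons)
  sat_neurons <- if (n_sat > 0) sort(sample(scene$n_neurons, n_sat)) else
    integer(0)
  n_cfos <- round(scene$cfos_fraction * scene$n_neurons)
  cfos_pos <- if (n_cfos > 0) sort(sample(scene$n_neurons, n_cfos)) else
    integer(0)

  # --- microglia somata ------------------------------------------------------
  m_r <- stats::runif(scene$n_microglia, scene$mg_soma_radius_um_range[1],
                      scene$mg_soma_radius_um_range[2])
  m_c <- matrix(NA_real_, scene$n_microglia, 3)
  partner <- rep(NA_integer_, scene$n_microglia)
  clear_of <- function(cand, r, skip_neuron = 0, min_clear = 2) {
    d <- sqrt(colSums((t(n_c) - cand)^2)) - n_r - r
    if (skip_neuron > 0) d <- d[-skip_neuron]
    all(d > min_clear)
  }
  overlap_um <- 0.8  # soma interdigitation depth for planted satellites
  for (j in seq_len(scene$n_microglia)) {
    placed <- FALSE
    if (j <= n_sat) {
      tgt <- sat_neurons[j]
      partner[j] <- tgt
      dist_cm <- n_r[tgt] + m_r[j] - overlap_um
      for (try in seq_len(max_tries)) {
        u <- rand_unit()
        cand <- n_c[tgt, ] + dist_cm * u
        inside <- all(cand >= m_r[j] * 0.5) && all(cand <= ext - m_r[j] * 0.5)
        ok <- inside && clear_of(cand, m_r[j], skip_neuron = tgt,
                                 min_clear = 0.5)
        if (ok && j > 1) {
          d <- sqrt(colSums((t(m_c[seq_len(j - 1), , drop = FALSE]) - cand)^2))
          ok <- all(d > m_r[seq_len(j - 1)] + m_r[j] + 0.5)
        }
        if (ok) { m_c[j, ] <- cand; placed <- TRUE; break }
      }
    } else {
      for (try in seq_len(max_tries)) {
        cand <- rand_center(m_r[j])
        ok <- clear_of(cand, m_r[j], min_clear = 2)
        if (ok && j > 1) {
          d <- sqrt(colSums((t(m_c[seq_len(j - 1), , drop = FALSE]) - cand)^2))
          ok <- all(d > m_r[seq_len(j - 1)] + m_r[j] + 0.5)
        }
        if (ok) { m_c[j, ] <- cand; placed <- TRUE; break }
      }
    }
    if (!placed)
      stop("could not place all microglia somata; use a larger grid")
  }

  # --- processes -------------------------------------------------------------
  filaments <- vector("list", scene$n_microglia)
  names(filaments) <- sprintf("mg-%02d", seq_len(scene$n_microglia))
  for (j in seq_len(scene$n_microglia)) {
    polys <- list()
    for (k in seq_len(scene$processes_per_microglia)) {
      if (!is.na(partner[j]) && k == 1) {
        polys[[k]] <- satellite_process(m_c[j, ], m_r[j],
                                        n_c[partner[j], ], n_r[partner[j]],
                                        ext)
      } else {
        polys[[k]] <- away_process(m_c[j, ], m_r[j], n_c, n_r, scene, ext,
                                   max_tries)
      }
    }
    filaments[[j]] <- polys
  }

  # --- rasterize -------------------------------------------------------------
  lev <- scene$intensity
  mk <- function() array(0, dim = shape)
  ch_mg <- mk(); ch_nn <- mk(); ch_cf <- mk()
  for (i in seq_len(scene$n_neurons)) {
    idx <- sphere_voxels(n_c[i, ], n_r[i], shape, vox)
    ch_nn[idx] <- lev$neuron
    if (i %in% cfos_pos) ch_cf[idx] <- lev$cfos_boost
  }
  for (j in seq_len(scene$n_microglia)) {
    idx <- sphere_voxels(m_c[j, ], m_r[j], shape, vox)
    ch_mg[idx] <- lev$microglia
    for (poly in filaments[[j]]) {
      idx <- tube_voxels(poly, scene$process_radius_um, shape, vox)
      ch_mg[idx] <- lev$microglia
    }
  }
  nvox <- prod(shape)
  addbg <- function(ch) ch + lev$background +
    if (lev$noise_sd > 0) stats::rnorm(nvox, sd = lev$noise_sd) else 0
  channels <- list(microglia = addbg(ch_mg), neurons = addbg(ch_nn),
                   cfos = addbg(ch_cf))

  truth <- list(
    neurons = data.frame(
      id = sprintf("n-%02d", seq_len(scene$n_neurons)),
      z_um = n_c[, 1], y_um = n_c[, 2], x_um = n_c[, 3],
      radius_um = n_r,
      satellite = seq_len(scene$n_neurons) %in% sat_neurons,
      partner_mg = names(filaments)[match(seq_len(scene$n_neurons), partner)],
      cfos = seq_len(scene$n_neurons) %in% cfos_pos),
    microglia = data.frame(
      id = names(filaments),
      z_um = m_c[, 1], y_um = m_c[, 2], x_um = m_c[, 3],
      radius_um = m_r,
      partner_neuron = ifelse(is.na(partner), NA_character_,
                              sprintf("n-%02d", partner))),
    filaments = filaments,
    scene = scene)

  structure(list(channels = channels, voxel_um = vox, truth = truth),
            class = "mg_stack")
}

#' @export
print.mg_stack <- function(x, ...) {
  cat(sprintf(
    "3D stack %s voxels (%s um), %d neurons (%d satellite, %d cfos+), %d microglia\n",
    paste(dim(x$channels$neurons), collapse = "x"),
    paste(x$voxel_um, collapse = "x"),
    nrow(x$truth$neurons), sum(x$truth$neurons$satellite),
    sum(x$truth$neurons$cfos), nrow(x$truth$microglia)))
  invisible(x)
}

rand_unit <- function() {
  repeat {
    u <- stats::rnorm(3)
    n <- sqrt(sum(u^2))
    if (n > 1e-8) return(u / n)
  }
}

# A process that starts on the microglia soma surface, runs to the partner
# neuron soma and hugs its surface for a short arc (touch + wrap).
satellite_process <- function(mc, mr, nc, nr, ext) {
  u <- (nc - mc); u <- u / sqrt(sum(u^2))
  p0 <- mc + mr * u
  # point just inside the partner soma surface
  p1 <- nc - (nr - 0.3) * u
  # wrap: two more points sliding along the soma surface
  w <- rand_unit(); w <- w - sum(w * u) * u
  if (sqrt(sum(w^2)) < 1e-6) w <- c(u[2], -u[1], 0)
  w <- w / sqrt(sum(w^2))
  surf <- function(a) nc - (nr + 0.1) * (cos(a) * u - sin(a) * w)
  pts <- rbind(p0, p1, surf(0.6), surf(1.2))
  clip_points(pts, ext)
}

# A process steered to keep clearance from every neuron soma.
away_process <- function(mc, mr, n_c, n_r, scene, ext, max_tries) {
  len <- stats::runif(1, scene$process_length_um_range[1],
                      scene$process_length_um_range[2])
  for (try in seq_len(max_tries)) {
    u <- rand_unit()
    seg <- len * c(0.4, 0.7, 1)
    bend <- rand_unit() * 0.25
    dirs <- rbind(u, u + bend, u + 2 * bend)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    pts <- rbind(mc + mr * u,
                 mc + mr * u + seg[1] * dirs[1, ],
                 mc + mr * u + seg[2] * dirs[2, ],
                 mc + mr * u + seg[3] * dirs[3, ])
    # sample densely and demand clearance from all neuron surfaces
    dense <- densify_polyline(pts, 0.5)
    d <- apply(dense, 1, function(p)
      min(sqrt(colSums((t(n_c) - p)^2)) - n_r))
    if (all(d > 1.5)) return(clip_points(pts, ext))
  }
  # fall back: point straight away from the nearest neuron
  dn <- sqrt(colSums((t(n_c) - mc)^2))
  u <- mc - n_c[which.min(dn), ]; u <- u / sqrt(sum(u^2))
  pts <- rbind(mc + mr * u, mc + (mr + len) * u)
  clip_points(pts, ext)
}

clip_points <- function(pts, ext) {
  for (a in 1:3) pts[, a] <- pmin(pmax(pts[, a], 0), ext[a])
  dimnames(pts) <- list(NULL, c("z_um", "y_um", "x_um"))
  pts
}

# Linear voxel indices of a solid sphere (center/radius in um, zyx order).
sphere_voxels <- function(center_um, r_um, shape, vox) {
  lo <- pmax(1, floor((center_um - r_um) / vox) + 1)
  hi <- pmin(shape, ceiling((center_um + r_um) / vox) + 1)
  if (any(lo > hi)) return(integer(0))
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  dz2 <- ((zi - 1) * vox[1] - center_um[1])^2
  dy2 <- ((yi - 1) * vox[2] - center_um[2])^2
  dx2 <- ((xi - 1) * vox[3] - center_um[3])^2
  d2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
  inside <- which(d2 <= r_um^2, arr.ind = TRUE)
  if (!nrow(inside)) return(integer(0))
  z <- zi[inside[, 1]]; y <- yi[inside[, 2]]; x <- xi[inside[, 3]]
  (x - 1) * shape[1] * shape[2] + (y - 1) * shape[1] + z
}

# Voxels of a tube of radius r along a polyline (points in um).
tube_voxels <- function(pts, r_um, shape, vox) {
  dense <- densify_polyline(pts, min(vox) / 2)
  idx <- lapply(seq_len(nrow(dense)), function(i)
    sphere_voxels(dense[i, ], r_um, shape, vox))
  unique(unlist(idx))
}

# Resample a polyline so consecutive points are at most `step` um apart.
densify_polyline <- function(pts, step) {
  out <- list(pts[1, , drop = FALSE])
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    L <- sqrt(sum((b - a)^2))
    n <- max(1, ceiling(L / step))
    s <- seq_len(n) / n
    out[[i + 1]] <- cbind(a[1] + s * (b[1] - a[1]),
                          a[2] + s * (b[2] - a[2]),
                          a[3] + s * (b[3] - a[3]))
  }
  m <- do.call(rbind, out)
  dimnames(m) <- list(NULL, c("z_um", "y_um", "x_um"))
  m
}
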