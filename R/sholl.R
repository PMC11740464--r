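#' Sholl profile of a microglia's processes
#'
#' Counts, for concentric spheres spaced `sphere_res_um` apart around the
#' soma centroid, how many times the process polylines cross each sphere.
#' Filaments whose total length is below `min_len_um` (default 0.9 um) are
#' discarded before counting, matching the filament-length filter of the
#' reference workflow. A crossing is a sign change of the distance-to-centroid
#' along a polyline segment; a vertex lying exactly on a sphere (tangency)
#' counts once.
#'
#' @param filaments List of polylines (matrices of zyx points in um).
#' @param centroid Soma centroid (z, y, x), um.
#' @param max_radius_um Largest sphere radius, um.
#' @param sphere_res_um Sphere spacing, um.
#' @param min_len_um Minimum filament length retained, um.
#' @return An object of class `sholl_profile`: data.frame with `radius_um`
#'   and `intersections`.
#' @export
sholl_profile <- function(filaments, centroid, max_radius_um,
                          sphere_res_um = 1, min_len_um = 0.9) {
  radii <- seq(sphere_res_um, max_radius_um, by = sphere_res_um)
  counts <- integer(length(radii))
  for (poly in filaments) {
    if (is.null(dim(poly)) || nrow(poly) < 2) next
    seg_len <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                             poly[-nrow(poly), , drop = FALSE])^2))
    if (sum(seg_len) < min_len_um) next
    d <- sqrt(colSums((t(poly) - centroid)^2))
    for (ri in seq_along(radii)) {
      r <- radii[ri]
      s <- d - r
      n1 <- length(s) - 1
      crossings <- sum(s[seq_len(n1)] * s[-1] < 0)
      # vertices exactly on the sphere count once each
      crossings <- crossings + sum(s == 0)
      counts[ri] <- counts[ri] + crossings
    }
  }
  structure(data.frame(radius_um = radii, intersections = counts),
            class = c("sholl_profile", "data.frame"))
}
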