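# Ligament CSA profiles: principal-axis alignment, incremental slicing,
# planar flattening, convex-hull area, and middle-50% averaging.

#' Align a point cloud so its longitudinal axis is +z
#'
#' Rotates the centred cloud so that the first principal direction maps to
#' +z. The axis sign is chosen so the longer tail of the z distribution
#' about its median is positive; the remaining principal directions become x
#' and y in a right-handed frame (in-plane rotation does not affect areas).
#'
#' @param cloud a `surface_point_cloud` (or an n x 3 matrix).
#' @return an object of class `aligned_cloud`: `points` (centred, rotated),
#'   `rotation` (the 3 x 3 matrix applied, rows = new axes), `axis_extent`
#'   `(z_min, z_max)`, `label`, and `near_isotropic` flag (TRUE when the
#'   first-to-second principal variance ratio is below 1.5).
#' @export
align_longitudinal <- function(cloud) {
  pts <- if (inherits(cloud, "surface_point_cloud")) cloud$points else as.matrix(cloud)
  label <- if (inherits(cloud, "surface_point_cloud")) cloud$label else ""
  if (nrow(pts) < 10L) stop("alignment needs >= 10 points")
  ctr <- colMeans(pts)
  x <- sweep(pts, 2L, ctr)
  eg <- eigen(crossprod(x) / (nrow(x) - 1L), symmetric = TRUE)
  if (eg$values[2L] <= eg$values[1L] * 1e-12)
    stop("alignment error: degenerate (collinear) point cloud")
  if (eg$values[3L] <= eg$values[1L] * 1e-12)
    stop("alignment error: degenerate (coplanar) point cloud")
  near_iso <- eg$values[1L] / eg$values[2L] < 1.5
  if (near_iso)
    warning("near-isotropic cloud: principal variance ratio ",
            sprintf("%.2f", eg$values[1L] / eg$values[2L]), " < 1.5")
  zax <- eg$vectors[, 1L]
  z <- as.vector(x %*% zax)
  if ((max(z) - stats::median(z)) < (stats::median(z) - min(z))) zax <- -zax
  xax <- eg$vectors[, 2L]
  yax <- c(zax[2L] * xax[3L] - zax[3L] * xax[2L],
           zax[3L] * xax[1L] - zax[1L] * xax[3L],
           zax[1L] * xax[2L] - zax[2L] * xax[1L])
  R <- rbind(x = xax, y = yax, z = zax)
  ap <- x %*% t(R)
  colnames(ap) <- c("x", "y", "z")
  structure(list(points = ap, rotation = R,
                 axis_extent = range(ap[, 3L]), label = label,
                 near_isotropic = near_iso),
            class = "aligned_cloud")
}

#' Slice an aligned cloud into axial bins
#'
#' Contiguous half-open bins `[z_min + k*increment, z_min + (k+1)*increment)`
#' partition the occupied extent; points exactly at `z_max` join the last
#' bin, so every point lands in exactly one slice. Slice CSA is the convex
#' hull area of the slice's points flattened onto x-y ([slice_csa()]);
#' slices with fewer than 3 points get a missing CSA, never zero.
#'
#' @param aligned an `aligned_cloud`.
#' @param increment slice thickness, mm (0.1 rat, 0.05 mouse).
#' @return an object of class `sliced_profile`: a data frame `slices` with
#'   columns `z_center`, `point_count`, `csa` plus fields `increment`,
#'   `label`, and the per-slice point sets (for audit).
#' @export
slice_along_axis <- function(aligned, increment) {
  stopifnot(inherits(aligned, "aligned_cloud"), increment > 0)
  z <- aligned$points[, 3L]
  z0 <- min(z)
  extent <- max(z) - z0
  if (increment > extent) {
    warning("increment ", increment, " mm exceeds axis extent ",
            sprintf("%.3g", extent), " mm: single-slice profile")
  }
  n_bin <- max(1L, as.integer(ceiling(extent / increment)))
  bin <- pmin(n_bin, as.integer(floor((z - z0) / increment)) + 1L)
  csa <- rep(NA_real_, n_bin)
  cnt <- integer(n_bin)
  sets <- vector("list", n_bin)
  for (k in seq_len(n_bin)) {
    sel <- bin == k
    cnt[k] <- sum(sel)
    xy <- aligned$points[sel, 1:2, drop = FALSE]
    sets[[k]] <- xy
    if (cnt[k] >= 3L) csa[k] <- slice_csa(aligned$points[sel, , drop = FALSE])
  }
  structure(list(slices = data.frame(
    z_center = z0 + (seq_len(n_bin) - 0.5) * increment,
    point_count = cnt, csa = csa),
    increment = increment, label = aligned$label, point_sets = sets,
    extent = range(z)),
    class = "sliced_profile")
}

#' Cross-sectional area of one slice
#'
#' Flattens the slice onto its x-y plane (z discarded after axis alignment
#' the slice normal is z by construction) and returns the shoelace area of
#' the 2D convex hull of the projected points. Ligament sections are
#' near-convex, and the hull is deterministic and parameter-free.
#'
#' @param slice_points n x 3 (or n x 2) matrix of points in one bin.
#' @return area in mm2, or `NA` for fewer than 3 distinct/non-collinear
#'   points.
#' @export
slice_csa <- function(slice_points) {
  xy <- as.matrix(slice_points)[, 1:2, drop = FALSE]
  if (nrow(xy) < 3L) return(NA_real_)
  convex_hull_area(xy)
}

#' Midsubstance CSA with middle-50% trimming
#'
#' Averages the CSA of slices whose centres fall in the central 50% of the
#' occupied axial extent (25th to 75th percentile of extent, bounds
#' inclusive); the flared ends near the bony insertions are excluded
#' entirely. The coefficient of variation is over the included slices.
#'
#' @param profile a `sliced_profile`.
#' @return an object of class `ligament_morphometry`: `midsubstance_csa`
#'   (mm2), `cv` (percent, n-1 SD), `n_slices_used`, `length` (occupied
#'   extent, mm), `label`.
#' @export
midsubstance_csa <- function(profile) {
  stopifnot(inherits(profile, "sliced_profile"))
  sl <- profile$slices
  valid <- !is.na(sl$csa)
  if (sum(valid) < 4L)
    stop("midsubstance error for '", profile$label, "': need >= 4 valid slices, have ",
         sum(valid))
  half <- profile$increment / 2
  ext <- profile$extent %||%
    c(min(sl$z_center) - half, max(sl$z_center) + half)
  z_lo <- ext[1L]
  z_hi <- ext[2L]
  b25 <- z_lo + 0.25 * (z_hi - z_lo)
  b75 <- z_lo + 0.75 * (z_hi - z_lo)
  inc <- valid & sl$z_center >= b25 & sl$z_center <= b75
  if (sum(inc) < 2L)
    stop("midsubstance error for '", profile$label,
         "': fewer than 2 valid slices inside the middle 50%")
  a <- sl$csa[inc]
  structure(list(midsubstance_csa = mean(a),
                 cv = 100 * stats::sd(a) / mean(a),
                 n_slices_used = sum(inc),
                 length = z_hi - z_lo,
                 label = profile$label),
            class = "ligament_morphometry")
}

#' @export
print.ligament_morphometry <- function(x, ...) {
  cat(sprintf("ligament_morphometry '%s': midsubstance CSA %.4g mm2 (CV %.1f%%, %d slices, length %.3g mm)\n",
              x$label, x$midsubstance_csa, x$cv, x$n_slices_used, x$length))
  invisible(x)
}

#' Full ligament measurement pipeline for one mesh
#'
#' Convenience wrapper: mesh -> point cloud -> longitudinal alignment ->
#' slicing at the species increment -> midsubstance CSA.
#'
#' @param mesh a `triangle_mesh`.
#' @param increment slice thickness in mm; default chosen from `species`.
#' @param species `"rat"` or `"mouse"` (sets the default increment).
#' @return a `ligament_morphometry`.
#' @export
measure_ligament <- function(mesh, increment = NULL,
                             species = c("rat", "mouse")) {
  increment <- increment %||% species_increment(match.arg(species))
  midsubstance_csa(slice_along_axis(align_longitudinal(mesh_to_points(mesh)),
                                    increment))
}
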