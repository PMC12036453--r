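# Tibial plateau footprint area and CSA normalization.

#' Footprint area from a single-slice voxel mask
#'
#' The segmentation volume divided by the voxel height: with occupied count
#' `c` and voxel size `(dx, dy, dz)`, area = `c * dx * dy * dz / dz =
#' c * dx * dy`. A mask spanning more than one axial slice triggers a
#' warning but is handled by the same volume/height contract.
#'
#' @param mask a `voxel_mask`.
#' @return an object of class `footprint_area`: `area` (mm2), `source`
#'   (`"voxel_mask"`), `voxel_size`.
#' @export
footprint_from_mask <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  ax <- match("axial", mask$axis_roles)
  n_slices <- sum(apply(mask$occupancy, ax, any))
  if (n_slices > 1L)
    warning("mask occupies ", n_slices,
            " axial slices; expected a single-slice segmentation")
  count <- sum(mask$occupancy)
  if (count == 0L) stop("empty mask")
  inplane <- prod(mask$voxel_size[-ax])
  structure(list(area = count * inplane, source = "voxel_mask",
                 voxel_size = mask$voxel_size, n_voxels = count),
            class = "footprint_area")
}

#' Footprint area from a planar bone trace
#'
#' Shoelace area of a simple polygon traced on a single image, scaled by the
#' pixel size (vertices are given in pixel units).
#'
#' @param polygon ordered two-column matrix of vertices (pixels).
#' @param pixel_size pixel edge length, mm.
#' @return a `footprint_area` with `source = "planar_trace"`.
#' @export
footprint_from_trace <- function(polygon, pixel_size = 1) {
  xy <- as.matrix(polygon)
  if (ncol(xy) != 2L || nrow(xy) < 3L)
    stop("trace must be an ordered polygon with >= 3 two-column vertices")
  if (polygon_self_intersects(xy)) stop("self-intersecting trace polygon")
  structure(list(area = polygon_area(xy) * pixel_size^2,
                 source = "planar_trace", n_vertices = nrow(xy)),
            class = "footprint_area")
}

#' Segment-intersection test over non-adjacent polygon edges
#' @noRd
polygon_self_intersects <- function(xy) {
  n <- nrow(xy)
  a <- xy
  b <- xy[c(2:n, 1L), , drop = FALSE]
  cross2 <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]   # skip edges sharing a vertex
    for (j in js) {
      d1 <- cross2(a[i, 1L], a[i, 2L], b[i, 1L], b[i, 2L], a[j, 1L], a[j, 2L])
      d2 <- cross2(a[i, 1L], a[i, 2L], b[i, 1L], b[i, 2L], b[j, 1L], b[j, 2L])
      d3 <- cross2(a[j, 1L], a[j, 2L], b[j, 1L], b[j, 2L], a[i, 1L], a[i, 2L])
      d4 <- cross2(a[j, 1L], a[j, 2L], b[j, 1L], b[j, 2L], b[i, 1L], b[i, 2L])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Normalize a ligament CSA by a plateau footprint
#'
#' @param csa ligament cross-sectional area, mm2 (>= 0).
#' @param footprint a `footprint_area` or a positive number (mm2).
#' @return an object of class `normalized_csa`: `csa`, `footprint`, and
#'   `normalized` = `100 * csa / footprint`, in percent (Table-style 0-100
#'   scale).
#' @export
normalize_csa <- function(csa, footprint) {
  fp <- if (inherits(footprint, "footprint_area")) footprint$area else as.numeric(footprint)
  if (!is.finite(fp) || fp <= 0) stop("footprint area must be positive")
  if (!is.finite(csa) || csa < 0) stop("csa must be non-negative")
  structure(list(csa = csa, footprint = fp,
                 normalized = 100 * csa / fp),
            class = "normalized_csa")
}

#' Join ligament measurements with footprints per specimen
#'
#' Per-specimen normalization (each knee's CSA over its own footprint), the
#' quantity group statistics are computed on; the ratio-of-group-means is
#' also reported for cross-checks.
#'
#' @param csa_table data frame with columns `specimen_id`, `tissue`,
#'   `midsubstance_csa_mm2`.
#' @param footprint_table data frame with columns `specimen_id`,
#'   `footprint_mm2`.
#' @return the csa table with added columns `footprint_mm2` and
#'   `normalized_pct`, plus attribute `ratio_of_means_pct` (per tissue).
#' @export
normalize_cohort <- function(csa_table, footprint_table) {
  m <- merge(csa_table, footprint_table, by = "specimen_id")
  m$normalized_pct <- 100 * m$midsubstance_csa_mm2 / m$footprint_mm2
  rom <- vapply(split(m, m$tissue), function(d)
    100 * mean(d$midsubstance_csa_mm2) / mean(d$footprint_mm2), numeric(1L))
  attr(m, "ratio_of_means_pct") <- rom
  m
}
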