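# Meniscus regional morphometry: anatomic alignment, middle-three
# coronal/sagittal slice selection, and ten-station height/width
# measurement per slice.

#' Align a meniscus cloud to the anatomic frame
#'
#' Maps the principal plane of the C-shaped cloud to x-y (smallest-variance
#' direction becomes z), fits a circle to the projected arc, and orients the
#' in-plane axes so the arc's bulge (central body) points along +x for a
#' lateral meniscus and -x for a medial one (right-knee convention:
#' +x lateral, +y anterior, +z superior). The z sign is chosen so the
#' wedge's wide base faces -z (tibial side), judged by which half of the
#' cloud has the larger in-plane spread. The in-plane origin is the fitted
#' arc centre.
#'
#' @param cloud a `surface_point_cloud` (or an n x 3 matrix).
#' @param side `"medial"` or `"lateral"`.
#' @return an object of class `meniscus_frame`: `points` (n x 3 in anatomic
#'   frame), `side`, `rotation` (matrix applied), `arc_radius` (fitted).
#' @export
align_meniscus <- function(cloud, side = c("medial", "lateral")) {
  side <- match.arg(side)
  pts <- if (inherits(cloud, "surface_point_cloud")) cloud$points else as.matrix(cloud)
  if (nrow(pts) < 100L) stop("meniscus alignment needs >= 100 points")
  ctr <- colMeans(pts)
  x <- sweep(pts, 2L, ctr)
  eg <- eigen(crossprod(x) / (nrow(x) - 1L), symmetric = TRUE)
  if (eg$values[1L] <= 0 || eg$values[2L] / eg$values[1L] < 1e-10)
    stop("alignment error: degenerate meniscus cloud")
  if (eg$values[3L] / eg$values[1L] > 0.6)
    stop("alignment error: cloud has no principal plane (near-spherical)")
  zax <- eg$vectors[, 3L]
  e1 <- eg$vectors[, 1L]
  e2 <- eg$vectors[, 2L]
  p1 <- as.vector(x %*% e1)
  p2 <- as.vector(x %*% e2)
  cf <- fit_circle(p1, p2)
  # bulge = direction opposite the arc's angular gap (the C opening), found
  # as the largest empty angular interval about the fitted centre; robust to
  # uneven surface sampling
  ang <- sort(atan2(p2 - cf[2L], p1 - cf[1L]))
  gaps <- c(diff(ang), ang[1L] + 2 * pi - ang[length(ang)])
  gi <- which.max(gaps)
  if (gaps[gi] < 10 * pi / 180)
    stop("alignment error: cannot identify the arc opening (closed ring?)")
  gap_mid <- ang[gi] + gaps[gi] / 2
  bulge <- -(cos(gap_mid) * e1 + sin(gap_mid) * e2)
  bulge <- bulge / sqrt(sum(bulge^2))
  sgn <- if (side == "lateral") 1 else -1
  xax <- sgn * bulge
  yax <- cross3(zax, xax)
  # z sign: wide base (larger in-plane spread) must face -z
  zc <- as.vector(x %*% zax)
  r_in <- sqrt((p1 - cf[1L])^2 + (p2 - cf[2L])^2)
  lo <- zc <= stats::median(zc)
  if (diff(range(r_in[lo])) < diff(range(r_in[!lo]))) {
    zax <- -zax
    yax <- -yax          # keep the frame right-handed without moving x
  }
  R <- rbind(x = xax, y = yax, z = zax)
  ap <- x %*% t(R)
  # in-plane origin at the fitted arc centre, z origin at the cloud centroid
  ctr2 <- fit_circle(ap[, 1L], ap[, 2L])
  ap[, 1L] <- ap[, 1L] - ctr2[1L]
  ap[, 2L] <- ap[, 2L] - ctr2[2L]
  colnames(ap) <- c("x", "y", "z")
  structure(list(points = ap, side = side, rotation = R,
                 arc_radius = ctr2[3L]),
            class = "meniscus_frame")
}

#' Algebraic (Kasa) circle fit; returns (cx, cy, r)
#' @noRd
fit_circle <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  s <- stats::lm.fit(A, b)$coefficients
  c(s[1L], s[2L], sqrt(max(s[3L] + s[1L]^2 + s[2L]^2, 0)))
}

#' @noRd
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Select the middle-three slices for a meniscus region
#'
#' Central region: three adjacent coronal (y) bins centred on the median y
#' of the arc's apex (the medial-most or lateral-most tenth of the cloud),
#' keeping only bulge-side points. Anterior/posterior horns: three adjacent
#' sagittal (x) bins centred on the median x of the full cloud, split by the
#' sign of y (anterior y > 0). Each slice is returned as a 2D point set
#' (horizontal in-slice axis first, height axis z second).
#'
#' @param frame a `meniscus_frame`.
#' @param region `"anterior"`, `"central"`, or `"posterior"`.
#' @param increment slice thickness, mm.
#' @return an object of class `region_slices`: `region`, `plane`, and
#'   `slices` (list of 3 two-column matrices).
#' @export
select_region_slices <- function(frame,
                                 region = c("anterior", "central", "posterior"),
                                 increment) {
  stopifnot(inherits(frame, "meniscus_frame"), increment > 0)
  region <- match.arg(region)
  p <- frame$points
  sgn <- if (frame$side == "lateral") 1 else -1
  if (region == "central") {
    sx <- sgn * p[, 1L]
    apex <- sx >= stats::quantile(sx, 0.9)
    y0 <- stats::median(p[apex, 2L])
    centers <- y0 + increment * (-1:1)
    keep <- sx > 0
    slices <- lapply(centers, function(cc) {
      sel <- keep & p[, 2L] >= cc - increment / 2 & p[, 2L] < cc + increment / 2
      p[sel, c(1L, 3L), drop = FALSE]
    })
    plane <- "coronal"
  } else {
    x0 <- stats::median(p[, 1L])
    centers <- x0 + increment * (-1:1)
    want_y <- if (region == "anterior") 1 else -1
    slices <- lapply(centers, function(cc) {
      sel <- p[, 1L] >= cc - increment / 2 & p[, 1L] < cc + increment / 2 &
        sign(p[, 2L]) == want_y
      p[sel, c(2L, 3L), drop = FALSE]
    })
    plane <- "sagittal"
  }
  empty <- vapply(slices, nrow, 1L) == 0L
  if (any(empty))
    stop("region '", region, "': empty ", plane, " slice at bin ",
         which(empty)[1L])
  structure(list(region = region, plane = plane, slices = slices,
                 centers = centers, increment = increment),
            class = "region_slices")
}

#' Ten-station height and width of one 2D slice
#'
#' Divides the horizontal extent into `n_stations` equal bins; each
#' station's height is the vertical (z) extent of its points. Symmetrically,
#' the vertical extent is divided into stations whose widths are horizontal
#' extents. Empty or single-point stations yield missing values, excluded
#' from the slice summary, which is the maximum station value (ten
#' measurements are taken per slice; the recorded slice value is their
#' maximum).
#'
#' @param slice two-column matrix (horizontal, vertical) in mm.
#' @param n_stations number of stations (default 10).
#' @return list with `height`, `width` (mm), and `stations` (data frame of
#'   the per-station extents).
#' @export
slice_height_width <- function(slice, n_stations = 10L) {
  s <- as.matrix(slice)
  if (nrow(s) < 10L) stop("measurement error: slice has fewer than 10 points")
  hr <- range(s[, 1L])
  vr <- range(s[, 2L])
  if (diff(hr) <= 0 || diff(vr) <= 0)
    stop("measurement error: slice has zero extent on an in-plane axis")
  bin_of <- function(v, r) pmin(n_stations, findInterval(
    v, seq(r[1L], r[2L], length.out = n_stations + 1L),
    rightmost.closed = TRUE))
  hb <- bin_of(s[, 1L], hr)
  vb <- bin_of(s[, 2L], vr)
  st_h <- st_w <- rep(NA_real_, n_stations)
  for (k in seq_len(n_stations)) {
    zk <- s[hb == k, 2L]
    if (length(zk) >= 1L) st_h[k] <- max(zk) - min(zk)
    xk <- s[vb == k, 1L]
    if (length(xk) >= 1L) st_w[k] <- max(xk) - min(xk)
  }
  if (all(is.na(st_h)) || all(is.na(st_w)))
    stop("measurement error: all stations empty on one axis")
  h <- max(st_h, na.rm = TRUE)
  w <- max(st_w, na.rm = TRUE)
  if (h == 0 || w == 0)
    warning("degenerate slice: zero station extents (sparse points?)")
  list(height = h, width = w,
       stations = data.frame(station = seq_len(n_stations),
                             height = st_h, width = st_w))
}

#' Regional height and width from three slices
#'
#' Measures each of the three slices with [slice_height_width()] and
#' averages: the region's height (width) is the arithmetic mean of the three
#' slice heights (widths). Per-slice values are retained for audit.
#'
#' @param slices a `region_slices`.
#' @param n_stations stations per slice (default 10).
#' @return an object of class `meniscus_region_measure`: `region`, `height`,
#'   `width` (mm), `per_slice` (3 x 2 matrix).
#' @export
region_measure <- function(slices, n_stations = 10L) {
  stopifnot(inherits(slices, "region_slices"))
  per <- lapply(seq_along(slices$slices), function(i) {
    tryCatch(slice_height_width(slices$slices[[i]], n_stations),
             error = function(e) stop("region '", slices$region, "', slice ",
                                      i, ": ", conditionMessage(e)))
  })
  hw <- vapply(per, function(m) c(m$height, m$width), numeric(2L))
  structure(list(region = slices$region,
                 height = mean(hw[1L, ]), width = mean(hw[2L, ]),
                 per_slice = t(hw)),
            class = "meniscus_region_measure")
}

#' Full meniscus measurement pipeline for one mesh
#'
#' @param mesh a `triangle_mesh` of a meniscus.
#' @param side `"medial"` or `"lateral"`; default inferred from the mesh
#'   label (`MED_MEN`/`LAT_MEN`).
#' @param increment slice thickness in mm; default from `species`.
#' @param species `"rat"` or `"mouse"`.
#' @param n_stations stations per slice.
#' @return data frame with one row per region: `side`, `region`,
#'   `height_mm`, `width_mm`, and per-slice audit columns.
#' @export
measure_meniscus <- function(mesh, side = NULL, increment = NULL,
                             species = c("rat", "mouse"), n_stations = 10L) {
  increment <- increment %||% species_increment(match.arg(species))
  side <- side %||% switch(mesh$label, MED_MEN = "medial",
                           LAT_MEN = "lateral",
                           stop("cannot infer side from label '", mesh$label, "'"))
  frame <- align_meniscus(mesh_to_points(mesh), side)
  rows <- lapply(c("anterior", "central", "posterior"), function(rg) {
    m <- region_measure(select_region_slices(frame, rg, increment), n_stations)
    data.frame(side = side, region = rg, height_mm = m$height,
               width_mm = m$width,
               h1 = m$per_slice[1L, 1L], h2 = m$per_slice[2L, 1L],
               h3 = m$per_slice[3L, 1L],
               w1 = m$per_slice[1L, 2L], w2 = m$per_slice[2L, 2L],
               w3 = m$per_slice[3L, 2L])
  })
  do.call(rbind, rows)
}
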