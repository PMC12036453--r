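# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Gift-wrapping (Jarvis march) convex hull + shoelace area.
oracle_hull_area <- function(xy) {
  xy <- unique(as.matrix(xy))
  n <- nrow(xy)
  if (n < 3L) return(NA_real_)
  start <- which.min(xy[, 1L] + 1e-12 * xy[, 2L])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1L) 2L else 1L
    for (j in seq_len(n)) {
      if (j == cur) next
      cr <- (xy[cand, 1L] - xy[cur, 1L]) * (xy[j, 2L] - xy[cur, 2L]) -
            (xy[cand, 2L] - xy[cur, 2L]) * (xy[j, 1L] - xy[cur, 1L])
      if (cand == cur || cr < 0 ||
          (cr == 0 && sum((xy[j, ] - xy[cur, ])^2) > sum((xy[cand, ] - xy[cur, ])^2)))
        cand <- j
    }
    cur <- cand
    if (cur == start) break
    if (length(hull) > n) stop("gift wrapping failed")
  }
  h <- xy[hull, , drop = FALSE]
  m <- nrow(h)
  i2 <- c(2:m, 1L)
  abs(sum(h[, 1L] * h[i2, 2L] - h[i2, 1L] * h[, 2L])) / 2
}

# Brute-force per-station extents for slice_height_width.
oracle_station_extents <- function(s, n_stations = 10L) {
  s <- as.matrix(s)
  hr <- range(s[, 1L]); vr <- range(s[, 2L])
  hedges <- seq(hr[1L], hr[2L], length.out = n_stations + 1L)
  vedges <- seq(vr[1L], vr[2L], length.out = n_stations + 1L)
  h <- w <- rep(NA_real_, n_stations)
  for (k in seq_len(n_stations)) {
    in_h <- s[, 1L] >= hedges[k] & (s[, 1L] < hedges[k + 1L] | k == n_stations)
    if (any(in_h)) h[k] <- diff(range(s[in_h, 2L]))
    in_v <- s[, 2L] >= vedges[k] & (s[, 2L] < vedges[k + 1L] | k == n_stations)
    if (any(in_v)) w[k] <- diff(range(s[in_v, 1L]))
  }
  list(height = max(h, na.rm = TRUE), width = max(w, na.rm = TRUE))
}

# Minimal independent binary STL reader (facet loop, no vectorization).
oracle_read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80L)
  nfac <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  tri <- matrix(0, 3L * nfac, 3L)
  for (i in seq_len(nfac)) {
    vals <- readBin(con, "double", 12L, size = 4L, endian = "little")
    readBin(con, "raw", 2L)
    tri[(3L * i - 2L):(3L * i), ] <- matrix(vals[4:12], 3L, byrow = TRUE)
  }
  tri
}

# Point-in-convex-polygon rasterization (mask of cell centres inside).
oracle_rasterize_convex <- function(poly, h, pad = 2L) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  xr <- range(poly[, 1L]); yr <- range(poly[, 2L])
  xs <- seq(floor(xr[1L] / h) - pad, ceiling(xr[2L] / h) + pad)
  ys <- seq(floor(yr[1L] / h) - pad, ceiling(yr[2L] / h) + pad)
  g <- expand.grid(x = (xs + 0.5) * h, y = (ys + 0.5) * h)
  inside <- rep(TRUE, nrow(g))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (poly[j, 1L] - poly[i, 1L]) * (g$y - poly[i, 2L]) -
          (poly[j, 2L] - poly[i, 2L]) * (g$x - poly[i, 1L])
    inside <- inside & cr >= 0
  }
  sum(inside)
}

# Small random closed tube mesh for round-trip properties.
random_test_mesh <- function(seed) {
  withr::with_seed(seed, {
    ax <- stats::rnorm(3L)
    stiflemorph::make_ligament(stiflemorph::ligament_spec(
      length = stats::runif(1L, 1, 3),
      area_profile = stats::runif(1L, 0.05, 0.4),
      axis_direction = ax / sqrt(sum(ax^2)),
      vertex_spacing = 0.02, seed = seed))
  })
}

rat_men_spec <- function(side = "lateral", seed = 1L, scale = 1,
                         perturb = 15) {
  stiflemorph::meniscus_spec(
    side = side, arc_radius = 2,
    height_field = stiflemorph::regional_field(0.82 * scale, 0.82 * scale),
    width_field = stiflemorph::regional_field(0.70 * scale, 1.18 * scale,
                                              1.13 * scale),
    vertex_spacing = 0.025, seed = seed, perturb_deg = perturb)
}
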