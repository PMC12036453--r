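# Seeded synthetic tissue geometries with exact ground truth.
#
# The generator stands in for MRI segmentations: ligaments are swept tubes
# with a prescribed cross-sectional-area profile, menisci are C-shaped
# wedges with prescribed regional height/width fields, plateaus are
# single-slice voxel masks. Every size parameter defaults to the published
# rodent scales (rat: CSA 0.17-0.35 mm2, 0.1 mm slices; mouse: CSA
# 0.029-0.054 mm2, 0.05 mm slices).

#' Ligament generator specification
#'
#' @param length tube length in mm.
#' @param area_profile true cross-sectional area along the tube: a single
#'   number (constant area, mm2), a function of normalized axial position
#'   `u` in `[0,1]`, or a two-column table `(u, area)` interpolated linearly.
#' @param section_shape `"circle"` or `"ellipse"`.
#' @param aspect major/minor semi-axis ratio for elliptical sections.
#' @param axis_direction unit 3-vector the tube axis points along.
#' @param vertex_spacing target spacing between mesh vertices in mm; must be
#'   at most a quarter of the slice increment the mesh will be analysed at.
#' @param seed integer seed controlling the random centroid offset.
#' @param label,species_tag annotations for the resulting mesh.
#' @return an object of class `ligament_spec`.
#' @export
ligament_spec <- function(length = 4, area_profile = 0.26,
                          section_shape = c("circle", "ellipse"), aspect = 1,
                          axis_direction = c(0, 0, 1), vertex_spacing = 0.025,
                          seed = 1L, label = "ACL", species_tag = "rat") {
  section_shape <- match.arg(section_shape)
  if (length <= 0) stop("ligament length must be positive")
  if (vertex_spacing <= 0) stop("vertex_spacing must be positive")
  if (section_shape == "circle") aspect <- 1
  if (aspect < 1) stop("aspect must be >= 1 (major/minor)")
  prof <- as_area_profile(area_profile)
  u <- seq(0, 1, length.out = 257L)
  if (any(prof(u) <= 0)) stop("area_profile must be positive on [0,1]")
  structure(list(length = length, area_profile = prof,
                 section_shape = section_shape, aspect = aspect,
                 axis_direction = axis_direction / sqrt(sum(axis_direction^2)),
                 vertex_spacing = vertex_spacing, seed = as.integer(seed),
                 label = label, species_tag = species_tag),
            class = "ligament_spec")
}

#' @noRd
as_area_profile <- function(p) {
  if (is.function(p)) return(p)
  if (is.numeric(p) && length(p) == 1L) {
    force(p)
    return(function(u) rep(p, length(u)))
  }
  tab <- as.matrix(p)
  if (ncol(tab) != 2L) stop("area_profile table must have columns (u, area)")
  stats::approxfun(tab[, 1L], tab[, 2L], rule = 2L)
}

#' Flared area profile with a constant midsubstance
#'
#' Piecewise-linear profile equal to `a0` on `[0.25, 0.75]` and ramping to
#' `flare * a0` at both ends — the idealization of a ligament that widens at
#' its bony insertions, whose true midsubstance CSA is `a0` exactly.
#'
#' @param a0 midsubstance area, mm2.
#' @param flare end-area multiplier (>= 1).
#' @return a function of `u`.
#' @export
flared_profile <- function(a0, flare = 1.5) {
  force(a0); force(flare)
  function(u) {
    ramp <- pmax(0, (abs(u - 0.5) - 0.25) / 0.25)
    a0 * (1 + (flare - 1) * ramp)
  }
}

#' Generate a ligament tube mesh
#'
#' Sweeps a polygonal section (at least a 64-gon) along the axis. Section
#' semi-axes are scaled by the polygon-to-ellipse area correction
#' `sqrt((2*pi/n)/sin(2*pi/n))` so the area of the polygon actually built
#' equals `area_profile(u)` exactly — "truth" refers to the built polygon.
#' The mesh is closed (end caps), oriented along `axis_direction`, and its
#' centroid sits at a seeded random offset.
#'
#' @param spec a [ligament_spec()].
#' @return a `triangle_mesh` carrying a `truth` attribute with
#'   `mid_csa` (exact midsubstance area, mm2), `length`, and
#'   `axis_direction`.
#' @export
make_ligament <- function(spec) {
  stopifnot(inherits(spec, "ligament_spec"))
  vs <- spec$vertex_spacing
  u_chk <- seq(0, 1, length.out = 513L)
  a_min <- min(spec$area_profile(u_chk))
  # smallest section controls circumferential fidelity; a regular n-gon is
  # within 0.5% of the ellipse area only for n >= 37
  per_min <- ellipse_perimeter(section_semiaxes(a_min, spec$aspect))
  n_req <- 37L
  if (ceiling(per_min / vs) < n_req && vs > per_min / n_req)
    stop(sprintf(paste0("vertex_spacing %.4g mm too coarse for 0.5%% area ",
                        "fidelity; need <= %.4g mm"), vs, per_min / n_req))
  per_max <- ellipse_perimeter(section_semiaxes(max(spec$area_profile(u_chk)),
                                                spec$aspect))
  n_seg <- max(64L, as.integer(ceiling(per_max / vs)))
  n_ring <- max(9L, as.integer(ceiling(spec$length / vs)) + 1L)
  zs <- seq(0, spec$length, length.out = n_ring)
  u <- zs / spec$length
  areas <- spec$area_profile(u)
  # polygon area of an n-gon inscribed at uniform angles is
  # (n/2) a b sin(2 pi/n); correct ab so the polygon area is exact
  corr <- (2 * pi / n_seg) / sin(2 * pi / n_seg)
  ab <- areas / pi * corr
  b <- sqrt(ab / spec$aspect)
  a <- spec$aspect * b
  t <- 2 * pi * (seq_len(n_seg) - 1L) / n_seg
  x <- as.vector(outer(cos(t), a))         # n_seg x n_ring, column-major
  y <- as.vector(outer(sin(t), b))
  z <- rep(zs, each = n_seg)
  v <- cbind(x, y, z)
  f <- tube_faces(n_seg, n_ring, closed_ring = TRUE)
  # end caps: fan to ring-center vertices
  c1 <- nrow(v) + 1L
  c2 <- nrow(v) + 2L
  v <- rbind(v, c(0, 0, 0), c(0, 0, spec$length))
  ring1 <- seq_len(n_seg)
  ringN <- (n_ring - 1L) * n_seg + seq_len(n_seg)
  f <- rbind(f,
             cbind(c1, ring1, c(ring1[-1L], ring1[1L])),
             cbind(c2, c(ringN[-1L], ringN[1L]), ringN))
  # orient along axis_direction, centre, seeded offset
  R <- rotation_between(c(0, 0, 1), spec$axis_direction)
  v <- sweep(v, 2L, c(0, 0, spec$length / 2)) %*% t(R)
  off <- with_seed(spec$seed, stats::runif(3L, -1, 1) * spec$length / 2)
  v <- sweep(v, 2L, off, `+`)
  mesh <- triangle_mesh(v, f, label = spec$label,
                        species_tag = spec$species_tag)
  u_mid <- seq(0.25, 0.75, length.out = 513L)
  attr(mesh, "truth") <- list(mid_csa = mean(spec$area_profile(u_mid)),
                              length = spec$length,
                              axis_direction = spec$axis_direction)
  mesh
}

#' @noRd
section_semiaxes <- function(area, aspect) {
  b <- sqrt(area / (pi * aspect))
  c(a = aspect * b, b = b)
}

#' Ramanujan approximation; ample for spacing decisions
#' @noRd
ellipse_perimeter <- function(ax) {
  a <- ax[[1L]]; b <- ax[[2L]]
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Quad strip faces for a swept ring
#' @noRd
tube_faces <- function(n_seg, n_ring, closed_ring = TRUE) {
  j <- seq_len(n_seg)
  jn <- if (closed_ring) c(j[-1L], j[1L]) else j + 1L
  base <- rep((seq_len(n_ring - 1L) - 1L) * n_seg, each = n_seg)
  v00 <- base + j
  v01 <- base + jn
  v10 <- base + n_seg + j
  v11 <- base + n_seg + jn
  rbind(cbind(v00, v01, v11), cbind(v00, v11, v10))
}

# ---- Menisci ------------------------------------------------------------

#' Meniscus generator specification
#'
#' The meniscus is modelled as a wedge section swept along a circular arc in
#' the transverse plane: apex (central body) at the extreme lateral (+x) or
#' medial (-x) coordinate, anterior horn at positive y, posterior horn at
#' negative y, wide base facing -z (tibial side).
#'
#' @param side `"medial"` or `"lateral"`.
#' @param arc_radius centreline radius of the arc, mm.
#' @param arc_span angular coverage in degrees (0, 330]. The default 320
#'   leaves a 40 degree gap between the horn tips so that mid-body sagittal
#'   slices cut the horn limbs nearly transversely, as the measurement
#'   protocol assumes.
#' @param height_field wedge height versus arc angle: a number or a function
#'   of the signed angle theta in degrees (0 = central body, positive =
#'   anterior).
#' @param width_field radial wedge width versus arc angle; same forms.
#' @param wedge_taper inner-rim height as a fraction of outer-rim height.
#' @param vertex_spacing target mesh vertex spacing, mm.
#' @param seed integer seed (random centroid offset; optional perturbation).
#' @param perturb_deg magnitude of a seeded random rigid rotation applied to
#'   the finished mesh (default 0; the cohort generator uses up to 15 so the
#'   alignment code is genuinely exercised).
#' @param species_tag annotation.
#' @return an object of class `meniscus_spec`.
#' @export
meniscus_spec <- function(side = c("medial", "lateral"), arc_radius = 2,
                          arc_span = 320, height_field = 0.82,
                          width_field = 1.0, wedge_taper = 0.25,
                          vertex_spacing = 0.025, seed = 1L, perturb_deg = 0,
                          species_tag = "rat") {
  side <- match.arg(side)
  if (arc_span <= 0 || arc_span > 330) stop("arc_span must be in (0, 330]")
  if (arc_radius <= 0) stop("arc_radius must be positive")
  if (wedge_taper < 0 || wedge_taper >= 1) stop("wedge_taper must be in [0,1)")
  hf <- as_angle_field(height_field)
  wf <- as_angle_field(width_field)
  th <- seq(-arc_span / 2, arc_span / 2, length.out = 181L)
  if (any(hf(th) <= 0) || any(wf(th) <= 0))
    stop("height_field and width_field must be positive over the span")
  structure(list(side = side, arc_radius = arc_radius, arc_span = arc_span,
                 height_field = hf, width_field = wf,
                 wedge_taper = wedge_taper, vertex_spacing = vertex_spacing,
                 seed = as.integer(seed), perturb_deg = perturb_deg,
                 species_tag = species_tag),
            class = "meniscus_spec")
}

#' @noRd
as_angle_field <- function(f) {
  if (is.function(f)) return(f)
  stopifnot(is.numeric(f), length(f) == 1L)
  force(f)
  function(theta) rep(f, length(theta))
}

#' Regional field reaching its horn values at the measurement stations
#'
#' Smoothstep in `|theta|` from `central` at the apex to the horn value at a
#' quarter of the span (where the middle-three sagittal slices land, see
#' [select_region_slices()]), constant beyond. The smoothstep has zero slope
#' at the apex and at the horn stations, so slices adjacent to a measurement
#' station see almost exactly the station's field value. Anterior
#' (`theta > 0`) and posterior horns may differ.
#'
#' @param central,anterior,posterior field values, mm.
#' @param arc_span span the field is built for, degrees.
#' @return a function of theta (degrees).
#' @export
regional_field <- function(central, anterior, posterior = anterior,
                           arc_span = 320) {
  force(central); force(anterior); force(posterior); force(arc_span)
  function(theta) {
    s <- pmin(1, abs(theta) / (arc_span / 4))
    s <- s * s * (3 - 2 * s)
    horn <- ifelse(theta >= 0, anterior, posterior)
    central + (horn - central) * s
  }
}

#' Generate a C-shaped wedge meniscus mesh
#'
#' @param spec a [meniscus_spec()].
#' @return a `triangle_mesh` (label `MED_MEN` or `LAT_MEN`) carrying a
#'   `truth` attribute with the spec and the nominal measurement angles
#'   (`0` for the central body, `+/- arc_span/4` for the horns).
#' @export
make_meniscus <- function(spec) {
  stopifnot(inherits(spec, "meniscus_spec"))
  vs <- spec$vertex_spacing
  span_rad <- spec$arc_span * pi / 180
  arc_len <- spec$arc_radius * span_rad
  n_arc <- max(16L, as.integer(ceiling(arc_len / vs)) + 1L)
  th <- seq(-span_rad / 2, span_rad / 2, length.out = n_arc)
  th_deg <- th * 180 / pi
  w <- spec$width_field(th_deg)
  h <- spec$height_field(th_deg)
  # fixed sample counts per cross-section edge (worst-case lengths)
  wm <- max(w); hm <- max(h); tp <- spec$wedge_taper
  n_bot <- max(3L, ceiling(wm / vs))
  n_out <- max(3L, ceiling(hm / vs))
  n_top <- max(3L, ceiling(sqrt(wm^2 + (hm * (1 - tp))^2) / vs))
  n_in <- max(2L, ceiling(hm * tp / vs))
  # unit cross-section boundary (w = h = 1), corners
  # (-1/2,0) (1/2,0) (1/2,1) (-1/2,tp); each edge includes start, not end
  edge <- function(p, q, n) {
    t <- (seq_len(n) - 1L) / n
    cbind(p[1L] + t * (q[1L] - p[1L]), p[2L] + t * (q[2L] - p[2L]))
  }
  loop <- rbind(edge(c(-0.5, 0), c(0.5, 0), n_bot),
                edge(c(0.5, 0), c(0.5, 1), n_out),
                edge(c(0.5, 1), c(-0.5, tp), n_top),
                edge(c(-0.5, tp), c(-0.5, 0), n_in))
  n_cs <- nrow(loop)
  # sweep: scale loop by (w, h) at each angle, bend around the arc
  r_off <- outer(loop[, 1L], w)            # n_cs x n_arc radial offsets
  zz <- outer(loop[, 2L], h)
  rad <- spec$arc_radius + r_off
  ct <- rep(cos(th), each = n_cs)
  st <- rep(sin(th), each = n_cs)
  v <- cbind(as.vector(rad) * ct, as.vector(rad) * st, as.vector(zz))
  f <- tube_faces(n_cs, n_arc, closed_ring = TRUE)
  # horn caps: fan to end-section centroids
  ring1 <- seq_len(n_cs)
  ringN <- (n_arc - 1L) * n_cs + seq_len(n_cs)
  c1 <- nrow(v) + 1L
  c2 <- nrow(v) + 2L
  v <- rbind(v, colMeans(v[ring1, , drop = FALSE]),
             colMeans(v[ringN, , drop = FALSE]))
  f <- rbind(f,
             cbind(c1, ring1, c(ring1[-1L], ring1[1L])),
             cbind(c2, c(ringN[-1L], ringN[1L]), ringN))
  if (spec$side == "medial") v[, 1L] <- -v[, 1L]   # mirror through sagittal plane
  # centre the wedge base plane at z = -mean height so the base faces -z
  v[, 3L] <- v[, 3L] - mean(zz)
  pert <- with_seed(spec$seed, {
    off <- stats::runif(3L, -1, 1) * spec$arc_radius / 2
    ax <- stats::rnorm(3L)
    ang <- stats::runif(1L, 0, spec$perturb_deg) * pi / 180
    list(off = off, R = rotation_about_axis(ax, ang))
  })
  if (spec$perturb_deg > 0) v <- v %*% t(pert$R)
  v <- sweep(v, 2L, pert$off, `+`)
  mesh <- triangle_mesh(v, f,
                        label = if (spec$side == "medial") "MED_MEN" else "LAT_MEN",
                        species_tag = spec$species_tag)
  attr(mesh, "truth") <- list(spec = spec,
                              theta_central = 0,
                              theta_anterior = spec$arc_span / 4,
                              theta_posterior = -spec$arc_span / 4,
                              rigid = list(offset = pert$off,
                                           rotation = if (spec$perturb_deg > 0)
                                             pert$R else diag(3)))
  mesh
}

#' Ground-truth regional measures for a generated meniscus
#'
#' Evaluates the spec's height/width fields at the nominal measurement
#' angles (apex and +/- span/4, where the middle-three slice rule lands for
#' an arc sampled uniformly in angle).
#'
#' @param mesh a mesh produced by [make_meniscus()].
#' @return data frame with columns `region`, `height_mm`, `width_mm`.
#' @export
meniscus_truth <- function(mesh) {
  tr <- attr(mesh, "truth")
  if (is.null(tr) || is.null(tr$spec)) stop("mesh has no meniscus truth record")
  sp <- tr$spec
  th <- c(central = tr$theta_central, anterior = tr$theta_anterior,
          posterior = tr$theta_posterior)
  data.frame(region = names(th),
             height_mm = as.numeric(sp$height_field(th)),
             width_mm = as.numeric(sp$width_field(th)),
             row.names = NULL)
}

# ---- Plateau masks and noise --------------------------------------------

#' Generate a single-slice tibial plateau voxel mask
#'
#' Occupies the `round(area / (dx*dy))` voxels closest to the grid centre of
#' a single axial slice (a rasterized disc), so the achievable area is the
#' closest multiple of the in-plane voxel area to the request.
#'
#' @param area target footprint area, mm2.
#' @param voxel_size `(dx, dy, dz)` in mm (default 0.1 mm isotropic).
#' @return a `voxel_mask` with attribute `achieved_area_mm2`.
#' @export
make_plateau_mask <- function(area, voxel_size = c(0.1, 0.1, 0.1)) {
  voxel_size <- as.numeric(voxel_size)
  pix <- voxel_size[1L] * voxel_size[2L]
  if (!is.finite(area) || area <= pix)
    stop("plateau area must exceed one in-plane voxel area (", pix, " mm2)")
  count <- max(1L, as.integer(round(area / pix)))
  n <- as.integer(ceiling(2 * sqrt(count / pi))) + 4L
  ctr <- (n + 1) / 2
  g <- expand.grid(i = seq_len(n), j = seq_len(n))
  d2 <- (g$i - ctr)^2 * voxel_size[1L]^2 + (g$j - ctr)^2 * voxel_size[2L]^2
  pick <- order(d2, g$i, g$j)[seq_len(count)]
  occ <- array(FALSE, dim = c(n, n, 1L))
  occ[cbind(g$i[pick], g$j[pick], 1L)] <- TRUE
  m <- voxel_mask(occ, voxel_size, c("sagittal", "coronal", "axial"))
  attr(m, "achieved_area_mm2") <- count * pix
  m
}

#' Displace mesh vertices along their outward normals
#'
#' Adds seeded zero-mean Gaussian displacement along per-vertex normals
#' (area-weighted average of incident face normals). `sigma = 0` returns the
#' mesh unchanged.
#'
#' @param mesh a `triangle_mesh`.
#' @param sigma displacement SD in mm.
#' @param seed integer seed.
#' @return a `triangle_mesh`.
#' @export
add_surface_noise <- function(mesh, sigma, seed = 1L) {
  stopifnot(inherits(mesh, "triangle_mesh"), sigma >= 0)
  if (sigma == 0) return(mesh)
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2L], ] - v[f[, 1L], ]
  e2 <- v[f[, 3L], ] - v[f[, 1L], ]
  fn <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  idx <- as.vector(f)
  vn <- rowsum(fn[rep(seq_len(nrow(f)), 3L), , drop = FALSE], idx)
  full <- matrix(0, nrow(v), 3L)
  full[as.integer(rownames(vn)), ] <- vn
  len <- sqrt(rowSums(full^2))
  full <- full / ifelse(len > 0, len, 1)
  d <- with_seed(seed, stats::rnorm(nrow(v), 0, sigma))
  out <- mesh
  out$vertices <- v + full * d
  attr(out, "truth") <- attr(mesh, "truth")
  out
}

# ---- Cohorts ------------------------------------------------------------

#' Species presets for the synthetic cohort
#'
#' Published mean morphometry used as generator targets: ligament
#' midsubstance CSA (mm2), meniscus regional widths and heights (mm), and
#' tibial plateau footprint (mm2), with the slice increment each species is
#' analysed at. Read from the plain-text preset table shipped with the
#' package.
#'
#' @param species `"rat"` or `"mouse"`, or `NULL` for the full table.
#' @return a data frame with columns `species`, `tissue`, `measure`,
#'   `mean`, `sd`.
#' @export
table1_presets <- function(species = NULL) {
  path <- system.file("extdata", "tissue_presets.csv", package = "stiflemorph",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(species)) tab <- tab[tab$species == species, , drop = FALSE]
  tab
}

#' Slice increment for a species
#' @param species `"rat"` (0.1 mm) or `"mouse"` (0.05 mm).
#' @return increment in mm.
#' @export
species_increment <- function(species = c("rat", "mouse")) {
  switch(match.arg(species), rat = 0.1, mouse = 0.05)
}

#' @noRd
cohort_scales <- function(species) {
  p <- table1_presets(species)
  val <- function(tissue, measure)
    p$mean[p$tissue == tissue & p$measure == measure]
  list(
    increment = species_increment(species),
    lig_csa = c(ACL = val("ACL", "csa"), PCL = val("PCL", "csa"),
                MCL = val("MCL", "csa"), LCL = val("LCL", "csa")),
    lig_length = if (species == "rat") 4 else 2,
    men_width = c(anterior = val("MEN", "width_anterior"),
                  central = val("MEN", "width_central"),
                  posterior = val("MEN", "width_posterior")),
    men_height = val("MEN", "height"),
    arc_radius = if (species == "rat") 2 else 0.9,
    plateau = val("PLATEAU", "area")
  )
}

#' Generate a synthetic cohort with ground truth
#'
#' Per specimen: four ligament tubes (flared ends, random axis direction),
#' two menisci (random rigid perturbation up to 15 degrees), and one plateau
#' mask. Tissue-mean sizes follow the species presets with between-specimen
#' lognormal scatter at coefficient of variation `cv` (default 25%, inside
#' the 16-40% range observed across rodent ligaments).
#'
#' @param species `"rat"` or `"mouse"`.
#' @param n number of specimens (>= 1).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param cv between-specimen coefficient of variation of size scalars.
#' @return a list with elements `specimens` (list per specimen: named
#'   `triangle_mesh`es for ACL/PCL/MCL/LCL/MED_MEN/LAT_MEN plus a
#'   `voxel_mask` `PLATEAU`) and `truth` (data frame: one row per generated
#'   geometry with its exact target morphometry).
#' @export
generate_cohort <- function(species = c("rat", "mouse"), n, seed = 1L,
                            cv = 0.25) {
  species <- match.arg(species)
  stopifnot(n >= 1)
  sc <- cohort_scales(species)
  vs <- sc$increment / 4
  sdlog <- sqrt(log(1 + cv^2))
  draws <- with_seed(seed, {
    list(scatter = matrix(stats::rlnorm(n * 7L, -sdlog^2 / 2, sdlog), n, 7L),
         axes = array(stats::rnorm(n * 4L * 3L), c(n, 4L, 3L)),
         sub = matrix(sample.int(.Machine$integer.max - 1L, n * 7L), n, 7L))
  })
  ligs <- names(sc$lig_csa)
  specimens <- vector("list", n)
  truth <- list()
  for (i in seq_len(n)) {
    tissues <- list()
    sid <- sprintf("%s%02d", toupper(substr(species, 1L, 1L)), i)
    for (k in seq_along(ligs)) {
      a0 <- sc$lig_csa[[k]] * draws$scatter[i, k]
      ax <- draws$axes[i, k, ]
      # spacing: quarter of the slice increment, tightened for thin tubes so
      # the smallest section still carries enough vertices for 0.5% fidelity
      vs_k <- min(vs, 2 * pi * sqrt(a0 / pi) / 40)
      mesh <- make_ligament(ligament_spec(
        length = sc$lig_length, area_profile = flared_profile(a0, 1.5),
        axis_direction = ax / sqrt(sum(ax^2)), vertex_spacing = vs_k,
        seed = draws$sub[i, k], label = ligs[k], species_tag = species))
      tissues[[ligs[k]]] <- mesh
      truth[[length(truth) + 1L]] <- data.frame(
        specimen_id = sid, tissue = ligs[k], measure = "mid_csa",
        region = NA_character_, value = attr(mesh, "truth")$mid_csa)
    }
    for (side in c("medial", "lateral")) {
      s <- draws$scatter[i, 5L + (side == "lateral")]
      wf <- regional_field(sc$men_width[["central"]] * s,
                           sc$men_width[["anterior"]] * s,
                           sc$men_width[["posterior"]] * s)
      hf <- regional_field(sc$men_height * s, sc$men_height * s)
      mesh <- make_meniscus(meniscus_spec(
        side = side, arc_radius = sc$arc_radius, height_field = hf,
        width_field = wf, vertex_spacing = vs,
        seed = draws$sub[i, 5L + (side == "lateral")], perturb_deg = 15,
        species_tag = species))
      tissues[[mesh$label]] <- mesh
      tru <- meniscus_truth(mesh)
      truth[[length(truth) + 1L]] <- data.frame(
        specimen_id = sid, tissue = mesh$label, measure = "height",
        region = tru$region, value = tru$height_mm)
      truth[[length(truth) + 1L]] <- data.frame(
        specimen_id = sid, tissue = mesh$label, measure = "width",
        region = tru$region, value = tru$width_mm)
    }
    vox <- if (species == "rat") c(0.1, 0.1, 0.1) else c(0.05, 0.05, 0.05)
    mask <- make_plateau_mask(sc$plateau * draws$scatter[i, 7L], vox)
    tissues[["PLATEAU"]] <- mask
    truth[[length(truth) + 1L]] <- data.frame(
      specimen_id = sid, tissue = "PLATEAU", measure = "area",
      region = NA_character_, value = attr(mask, "achieved_area_mm2"))
    specimens[[i]] <- tissues
    names(specimens)[i] <- sid
  }
  list(specimens = specimens, truth = do.call(rbind, truth),
       species = species, increment = sc$increment, seed = as.integer(seed))
}
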