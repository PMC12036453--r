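# Triangle-mesh and voxel-mask containers and their file formats.
#
# All coordinates are millimetres throughout the package. STL files carry no
# unit metadata; the 0.1 mm (rat) / 0.05 mm (mouse) slicing increments only
# make sense if meshes are exported in mm, so that convention is fixed here.

TISSUE_LABELS <- c("ACL", "PCL", "MCL", "LCL", "MED_MEN", "LAT_MEN", "PLATEAU")

#' Construct a triangle mesh
#'
#' A minimal triangle-mesh container for one segmented tissue. Vertices are
#' welded on construction: duplicated coordinate rows (exact bitwise match,
#' no epsilon merging — thin mouse-scale tissues must not collapse) are
#' merged and face indices remapped.
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param label tissue identifier; one of `"ACL"`, `"PCL"`, `"MCL"`, `"LCL"`,
#'   `"MED_MEN"`, `"LAT_MEN"`, `"PLATEAU"`, or any free-text label.
#' @param species_tag free-text species annotation (e.g. `"rat"`).
#' @param weld weld exactly-coincident vertices (default `TRUE`).
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces`, `label`, `species_tag`.
#' @export
triangle_mesh <- function(vertices, faces, label = "ACL", species_tag = "",
                          weld = TRUE) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (nrow(faces) && (any(faces < 1L) || any(faces > nrow(vertices))))
    stop("face index out of range")
  if (weld && nrow(vertices) > 0L) {
    key <- paste(sprintf("%a", vertices[, 1L]), sprintf("%a", vertices[, 2L]),
                 sprintf("%a", vertices[, 3L]))
    first <- !duplicated(key)
    map <- match(key, key[first])
    vertices <- vertices[first, , drop = FALSE]
    faces <- matrix(map[faces], ncol = 3L)
  }
  m <- structure(list(vertices = vertices, faces = faces,
                      label = as.character(label),
                      species_tag = as.character(species_tag)),
                 class = "triangle_mesh")
  validate_mesh(m)
  m
}

#' @noRd
validate_mesh <- function(m) {
  v <- m$vertices; f <- m$faces
  if (!all(is.finite(v))) stop("degenerate mesh: non-finite vertex coordinates")
  if (nrow(v) < 4L || nrow(f) < 4L)
    stop("degenerate mesh: need >= 4 vertices and >= 4 faces, got ",
         nrow(v), " / ", nrow(f))
  if (any(f < 1L) || any(f > nrow(v)))
    stop("face index out of range")
  if (any(f[, 1L] == f[, 2L] | f[, 1L] == f[, 3L] | f[, 2L] == f[, 3L]))
    stop("degenerate face: repeated vertex within a face")
  bb <- apply(v, 2L, range)
  if (sqrt(sum((bb[2L, ] - bb[1L, ])^2)) <= 0)
    stop("degenerate mesh: zero bounding-box diagonal")
  invisible(m)
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("triangle_mesh '%s'%s: %d vertices, %d faces, bbox %.3g mm\n",
              x$label,
              if (nzchar(x$species_tag)) paste0(" [", x$species_tag, "]") else "",
              nrow(x$vertices), nrow(x$faces),
              sqrt(sum((bb[2L, ] - bb[1L, ])^2))))
  invisible(x)
}

#' Convert a mesh to a surface point cloud
#'
#' The point cloud is exactly the welded vertex set of the mesh — a
#' deterministic choice (no face-area-weighted resampling); density
#' requirements are the responsibility of whoever built the mesh (the
#' synthetic generator guarantees vertex spacing of at most a quarter of the
#' slice increment).
#'
#' @param mesh a `triangle_mesh`.
#' @return an object of class `surface_point_cloud` with elements `points`
#'   (n x 3 matrix, mm), `label`, and cached `centroid`.
#' @export
mesh_to_points <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  validate_mesh(mesh)
  structure(list(points = mesh$vertices, label = mesh$label,
                 centroid = colMeans(mesh$vertices)),
            class = "surface_point_cloud")
}

#' @export
print.surface_point_cloud <- function(x, ...) {
  cat(sprintf("surface_point_cloud '%s': %d points, centroid (%.3f, %.3f, %.3f) mm\n",
              x$label, nrow(x$points), x$centroid[1L], x$centroid[2L], x$centroid[3L]))
  invisible(x)
}

# ---- STL ----------------------------------------------------------------

#' Read an STL file (binary or ASCII)
#'
#' Detects the variant from the file content (a file starting with `solid`
#' that parses as ASCII is read as ASCII; anything else as little-endian
#' binary). Duplicate vertices are welded exactly. Units are assumed mm.
#'
#' @param path path to an `.stl` file.
#' @param label,species_tag annotations attached to the mesh; `label`
#'   defaults to the file base name.
#' @return a `triangle_mesh`.
#' @export
read_stl <- function(path, label = NULL,
                     species_tag = "") {
  if (!file.exists(path)) stop("STL file not found: ", path)
  label <- label %||% tools::file_path_sans_ext(basename(path))
  head <- readBin(path, "raw", n = 80L)
  is_ascii <- length(head) >= 5L &&
    identical(rawToChar(head[1:5]), "solid") &&
    # binary files sometimes start with 'solid' too; require a 'facet' token
    # (or a file too small to hold a binary header at all)
    (file.size(path) < 84 ||
       grepl("facet", suppressWarnings(
         paste(readLines(path, n = 20L, warn = FALSE), collapse = " ")),
         fixed = TRUE))
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  if (nrow(tri) == 0L) stop("degenerate input: STL '", path, "' holds no facets")
  nf <- nrow(tri) / 3L
  triangle_mesh(tri, matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE),
                label = label, species_tag = species_tag)
}

#' @noRd
read_stl_binary <- function(path) {
  sz <- file.size(path)
  if (sz < 84) stop("STL format error in '", path, "': file truncated at byte ",
                    sz, " (need 84-byte header)")
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nfac <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  need <- 84 + 50 * as.numeric(nfac)
  if (sz < need)
    stop("STL format error in '", path, "': declared ", nfac,
         " facets but file truncated at byte ", sz, " (need ", need, ")")
  raw <- readBin(con, "raw", n = 50L * nfac)
  # each facet: 12 float32 (normal + 3 vertices) + uint16 attribute
  idx <- rep(seq_len(nfac) - 1L, each = 48L) * 50L + rep(1:48, nfac)
  vals <- readBin(raw[idx], "double", n = 12L * nfac, size = 4L,
                  endian = "little")
  m <- matrix(vals, ncol = 12L, byrow = TRUE)
  tri <- rbind(m[, 4:6, drop = FALSE], m[, 7:9, drop = FALSE],
               m[, 10:12, drop = FALSE])
  # interleave back into per-facet vertex order
  ord <- as.vector(t(matrix(seq_len(3L * nfac), ncol = 3L)))
  tri[ord, , drop = FALSE]
}

#' @noRd
read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3L != 0L)
    stop("STL format error in '", path, "': vertex count ", length(vl),
         " not a multiple of 3")
  toks <- strsplit(trimws(vl), "\\s+")
  bad <- which(vapply(toks, length, 1L) != 4L)
  if (length(bad))
    stop("STL format error in '", path, "': malformed vertex line ", bad[1L])
  matrix(as.numeric(unlist(lapply(toks, `[`, 2:4))), ncol = 3L, byrow = TRUE)
}

#' Write a mesh as binary STL
#'
#' Emits the standard little-endian binary layout: 80-byte header, uint32
#' facet count, then 50 bytes per facet. Coordinates are rounded to float32
#' (the format's precision); `read_stl(write_stl(m))` is the identity up to
#' vertex order and that rounding.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  validate_mesh(mesh)
  v <- mesh$vertices; f <- mesh$faces
  nfac <- nrow(f)
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  nrm <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
               e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
               e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / ifelse(len > 0, len, 1)
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  writeBin(as.integer(nfac), con, size = 4L, endian = "little")
  block <- cbind(nrm, a, b, cc)            # nfac x 12 float32 payload
  payload <- as.vector(t(block))
  # write facet-wise to interleave the 2-byte attribute counts
  fl <- writeBin(payload, raw(), size = 4L, endian = "little")
  fl <- matrix(fl, ncol = 48L, byrow = TRUE)
  out <- raw(50L * nfac)
  pos <- rep((seq_len(nfac) - 1L) * 50L, each = 48L) + rep(1:48, nfac)
  out[pos] <- as.vector(t(fl))
  writeBin(out, con)
  invisible(path)
}

# ---- Voxel masks --------------------------------------------------------

#' Construct a voxel mask
#'
#' @param occupancy 3D logical array of voxel occupancy.
#' @param voxel_size numeric length-3, voxel edge lengths `(dx, dy, dz)` mm.
#' @param axis_roles character length-3 naming the anatomical role of each
#'   grid axis; the axial slice normal must be labelled `"axial"`.
#' @return an object of class `voxel_mask`.
#' @export
voxel_mask <- function(occupancy, voxel_size,
                       axis_roles = c("sagittal", "coronal", "axial")) {
  occupancy <- as.array(occupancy)
  if (length(dim(occupancy)) != 3L) stop("occupancy must be a 3D array")
  storage.mode(occupancy) <- "logical"
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be three positive numbers (mm)")
  if (!any(occupancy)) stop("empty mask: no occupied voxel")
  if (!"axial" %in% axis_roles) stop("axis_roles must identify the axial axis")
  structure(list(occupancy = occupancy, voxel_size = voxel_size,
                 axis_roles = as.character(axis_roles)),
            class = "voxel_mask")
}

#' Write a voxel mask as occupied-voxel CSV plus JSON sidecar
#'
#' Plain-text on-disk form: `<path>` is a CSV of 1-based occupied voxel
#' indices (`i,j,k`) and `<path>.json` records grid dimensions, voxel size
#' and axis roles.
#'
#' @param mask a `voxel_mask`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_voxel_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  idx <- which(mask$occupancy, arr.ind = TRUE)
  colnames(idx) <- c("i", "j", "k")
  utils::write.csv(as.data.frame(idx), path, row.names = FALSE)
  jsonlite::write_json(
    list(dim = dim(mask$occupancy), voxel_size_mm = mask$voxel_size,
         axis_roles = mask$axis_roles),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a voxel mask written by [write_voxel_mask()]
#' @param path CSV path (the `<path>.json` sidecar must sit next to it).
#' @return a `voxel_mask`.
#' @export
read_voxel_mask <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path)) stop("mask CSV not found: ", path)
  if (!file.exists(side)) stop("mask sidecar not found: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  idx <- as.matrix(utils::read.csv(path))
  occ <- array(FALSE, dim = as.integer(meta$dim))
  occ[idx] <- TRUE
  voxel_mask(occ, meta$voxel_size_mm, meta$axis_roles)
}
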