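# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators are bit-reproducible
#' without disturbing the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Shoelace area of a polygon given in order
#' @noRd
polygon_area <- function(xy) {
  x <- xy[, 1L]
  y <- xy[, 2L]
  n <- length(x)
  if (n < 3L) return(0)
  i2 <- c(2:n, 1L)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' Area of the 2D convex hull of a point set (0 if degenerate)
#' @noRd
convex_hull_area <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 3L) return(NA_real_)
  h <- grDevices::chull(xy[, 1L], xy[, 2L])
  if (length(h) < 3L) return(NA_real_)
  a <- polygon_area(xy[h, , drop = FALSE])
  if (a <= 0) NA_real_ else a
}

#' Rotation matrix about an arbitrary unit axis (Rodrigues)
#' @noRd
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Random rotation matrix, uniform over SO(3), from the active RNG stream
#' @noRd
random_rotation <- function() {
  # QR of a Gaussian matrix with sign fix gives Haar-distributed Q
  q <- qr(matrix(stats::rnorm(9L), 3L))
  R <- qr.Q(q)
  R <- R %*% diag(sign(diag(qr.R(q))))
  if (det(R) < 0) R[, 3L] <- -R[, 3L]
  R
}

#' Rotation taking unit vector `from` to unit vector `to`
#' @noRd
rotation_between <- function(from, to) {
  from <- from / sqrt(sum(from^2))
  to <- to / sqrt(sum(to^2))
  v <- c(from[2L] * to[3L] - from[3L] * to[2L],
         from[3L] * to[1L] - from[1L] * to[3L],
         from[1L] * to[2L] - from[2L] * to[1L])
  s <- sqrt(sum(v^2))
  c_ <- sum(from * to)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3L))
    # antiparallel: rotate pi about any axis orthogonal to `from`
    ortho <- if (abs(from[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- ortho - sum(ortho * from) * from
    return(rotation_about_axis(axis, pi))
  }
  rotation_about_axis(v / s, atan2(s, c_))
}

#' @noRd
is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == 3L) &&
    max(abs(crossprod(R) - diag(3L))) < tol && abs(det(R) - 1) < tol
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
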