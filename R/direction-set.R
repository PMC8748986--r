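#' Build a quasi-uniform set of ray directions on the unit sphere
#'
#' Star-convex nucleus detectors encode each nucleus as a center plus a
#' fixed number of radial ray lengths (96 by default). The directions of
#' those rays are placed on a Fibonacci sphere, which is deterministic and
#' quasi-uniform, and triangulated by the convex hull of the direction
#' points. The triangulation is what turns ray lengths into a closed
#' surface mesh for volume, area and interpolation queries.
#'
#' @param n_rays Number of ray directions (>= 4; default 96).
#' @return An object of class `direction_set`: a list with `n_rays`,
#'   `directions` (an `n_rays` x 3 matrix of unit vectors), `faces`
#'   (an F x 3 integer matrix of direction indices, outward oriented,
#'   F = 2 * n_rays - 4), and precomputed per-face solve matrices used by
#'   [radial_extent()].
#' @examples
#' dirs <- direction_set(96)
#' nrow(dirs$faces) # 188
#' @export
direction_set <- function(n_rays = 96) {
  if (!is.numeric(n_rays) || length(n_rays) != 1 || n_rays < 4 ||
      n_rays != round(n_rays)) {
    stop("n_rays must be a single integer >= 4 (no closed triangulation exists below 4)")
  }
  n_rays <- as.integer(n_rays)
  i <- seq_len(n_rays) - 1
  z <- 1 - 2 * (i + 0.5) / n_rays
  golden <- pi * (3 - sqrt(5))
  theta <- golden * i
  rho <- sqrt(pmax(0, 1 - z^2))
  directions <- cbind(x = rho * cos(theta), y = rho * sin(theta), z = z)

  # The points are cospherical, which is maximally degenerate for a
  # Delaunay-based hull extraction; a tiny deterministic radial scaling
  # breaks ties without moving any point off its direction.
  eps <- 1e-9 * (1 + sin(7 * i + 1))
  res <- .delaunay3d_cpp(directions * (1 + eps), seq_len(n_rays))
  if (!isTRUE(res$ok) || nrow(res$hull) != 2L * n_rays - 4L) {
    stop("direction triangulation failed: got ", nrow(res$hull),
         " hull faces, expected ", 2L * n_rays - 4L)
  }
  faces <- res$hull
  dimnames(faces) <- NULL

  # orient every face outward (positive determinant seen from the origin)
  dets <- face_determinants(directions, faces)
  flip <- dets < 0
  if (any(flip)) {
    faces[flip, 2:3] <- faces[flip, 3:2]
    dets <- abs(dets)
  }
  if (any(dets <= 0)) stop("degenerate face in direction triangulation")

  # per-face inverse of the 3x3 direction matrix, for barycentric queries
  inv <- array(NA_real_, dim = c(3, 3, nrow(faces)))
  for (f in seq_len(nrow(faces))) {
    inv[, , f] <- solve(directions[faces[f, ], , drop = FALSE])
  }

  structure(
    list(n_rays = n_rays, directions = directions, faces = faces,
         face_det = dets, face_inv = inv),
    class = "direction_set"
  )
}

face_determinants <- function(directions, faces) {
  a <- directions[faces[, 1], , drop = FALSE]
  b <- directions[faces[, 2], , drop = FALSE]
  c_ <- directions[faces[, 3], , drop = FALSE]
  a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
}

#' Solid angles of the faces of a direction set
#'
#' Spherical-triangle solid angles by the van Oosterom-Strackee formula.
#' They sum to 4*pi for any closed triangulation of the sphere.
#'
#' @param dirs A [direction_set()].
#' @return Numeric vector of solid angles (steradians), one per face.
#' @export
face_solid_angles <- function(dirs) {
  stopifnot(inherits(dirs, "direction_set"))
  d <- dirs$directions
  f <- dirs$faces
  a <- d[f[, 1], , drop = FALSE]
  b <- d[f[, 2], , drop = FALSE]
  c_ <- d[f[, 3], , drop = FALSE]
  num <- dirs$face_det
  den <- 1 + rowSums(a * b) + rowSums(b * c_) + rowSums(c_ * a)
  2 * atan2(num, den)
}

#' @export
print.direction_set <- function(x, ...) {
  cat("<direction_set> ", x$n_rays, " rays, ", nrow(x$faces),
      " triangular faces\n", sep = "")
  invisible(x)
}

#' Serialize a direction set to JSON
#'
#' @param dirs A [direction_set()].
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_direction_set <- function(dirs, path) {
  stopifnot(inherits(dirs, "direction_set"))
  jsonlite::write_json(
    list(n_rays = dirs$n_rays,
         directions = unname(dirs$directions),
         faces = unname(dirs$faces)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a direction set from JSON
#'
#' Faces and precomputed matrices are rebuilt from the stored directions,
#' then checked against the stored faces.
#'
#' @param path File written by [write_direction_set()].
#' @return A `direction_set`.
#' @export
read_direction_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ds <- direction_set(obj$n_rays)
  if (max(abs(ds$directions - obj$directions)) > 1e-8) {
    stop("stored directions do not match the deterministic construction for n_rays = ",
         obj$n_rays)
  }
  ds
}
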