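#' Names of the ray-length columns of a shape table
#'
#' Shape tables store one nucleus per row: identifiers, center coordinates
#' `cx_um`, `cy_um`, `cz_um` (micrometres) and one positive ray length per
#' direction, in columns `r000`, `r001`, ...
#'
#' @param n_rays Number of rays.
#' @return Character vector of column names.
#' @export
ray_cols <- function(n_rays) {
  w <- max(3L, nchar(as.character(n_rays - 1L)))
  sprintf(paste0("r%0", w, "d"), seq_len(n_rays) - 1L)
}

#' Assemble a shape table from centers and a ray matrix
#'
#' @param centers n x 3 matrix of nucleus centers (micrometres).
#' @param rays n x n_rays matrix of positive ray lengths (micrometres).
#' @param image_id,nucleus_id Identifiers (recycled / defaulted).
#' @return A tibble in the standard shape-table layout.
#' @export
shape_table <- function(centers, rays, image_id = "img", nucleus_id = NULL) {
  centers <- rbind(centers)
  rays <- rbind(rays)
  stopifnot(ncol(centers) == 3, nrow(centers) == nrow(rays))
  if (any(!is.finite(rays)) || any(rays <= 0)) {
    stop("all ray lengths must be positive and finite")
  }
  n <- nrow(rays)
  out <- tibble::tibble(
    image_id = rep_len(as.character(image_id), n),
    nucleus_id = nucleus_id %||% seq_len(n),
    cx_um = centers[, 1], cy_um = centers[, 2], cz_um = centers[, 3]
  )
  rmat <- rays
  colnames(rmat) <- ray_cols(ncol(rays))
  dplyr::bind_cols(out, tibble::as_tibble(rmat))
}

ray_matrix <- function(shapes, dirs = NULL) {
  rc <- grep("^r[0-9]+$", names(shapes), value = TRUE)
  if (length(rc) == 0) stop("shape table has no ray columns (r000, r001, ...)")
  rc <- rc[order(as.integer(sub("^r", "", rc)))]
  if (!is.null(dirs) && length(rc) != dirs$n_rays) {
    stop("shape table has ", length(rc), " rays but the direction set has ",
         dirs$n_rays, " (shapes must conform to the direction set)")
  }
  m <- as.matrix(shapes[rc])
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("all ray lengths must be positive and finite")
  }
  m
}

centers_matrix <- function(shapes) {
  need <- c("cx_um", "cy_um", "cz_um")
  if (!all(need %in% names(shapes))) {
    stop("shape table must have columns cx_um, cy_um, cz_um")
  }
  m <- as.matrix(shapes[need])
  if (any(!is.finite(m))) stop("non-finite center coordinates")
  m
}

#' Volume, surface area and compactness of star-convex nuclei
#'
#' Each nucleus is the polyhedron whose vertices are `center + ray_i *
#' direction_i`, triangulated by the faces of the direction set. Volume is
#' the sum of signed tetrahedron volumes (center, three ray endpoints);
#' area the sum of triangle areas of the endpoint mesh; compactness the
#' sphericity index `(36 * pi * V^2)^(1/3) / A`, equal to 1 for a sphere.
#'
#' @param shapes Shape table (see [shape_table()]).
#' @param dirs A [direction_set()] the shapes conform to.
#' @return A tibble with `image_id`, `nucleus_id`, `volume` (um^3),
#'   `area` (um^2) and `compactness`.
#' @examples
#' dirs <- direction_set(96)
#' s <- shape_table(c(0, 0, 0), matrix(5, 1, 96))
#' shape_metrics(s, dirs) # close to the 5-um sphere: V 523.6, A 314.2
#' @export
shape_metrics <- function(shapes, dirs) {
  stopifnot(inherits(dirs, "direction_set"))
  rmat <- ray_matrix(shapes, dirs)
  f <- dirs$faces
  vol <- as.vector((rmat[, f[, 1], drop = FALSE] *
                    rmat[, f[, 2], drop = FALSE] *
                    rmat[, f[, 3], drop = FALSE]) %*% (dirs$face_det / 6))
  d <- dirs$directions
  area <- numeric(nrow(rmat))
  for (k in seq_len(nrow(f))) {
    p1 <- rmat[, f[k, 1]] %o% d[f[k, 1], ]
    e1 <- rmat[, f[k, 2]] %o% d[f[k, 2], ] - p1
    e2 <- rmat[, f[k, 3]] %o% d[f[k, 3], ] - p1
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    area <- area + 0.5 * sqrt(rowSums(cr^2))
  }
  tibble::tibble(
    image_id = shapes$image_id %||% rep("img", nrow(rmat)),
    nucleus_id = shapes$nucleus_id %||% seq_len(nrow(rmat)),
    volume = vol, area = area,
    compactness = compactness(vol, area)
  )
}

#' Sphericity (compactness) of a closed shape
#'
#' `(36 * pi * V^2)^(1/3) / A`: the surface area of the sphere with the
#' shape's volume divided by the shape's actual area. Equal to 1 for a
#' sphere (the equality case of the isoperimetric inequality), below 1
#' for every other physically realizable surface; flatter nuclei score
#' lower.
#'
#' @param volume Volume(s), um^3 (> 0).
#' @param area Surface area(s), um^2 (> 0).
#' @return Dimensionless compactness, same length as the inputs.
#' @examples
#' compactness(4 / 3 * pi * 5^3, 4 * pi * 5^2) # sphere: exactly 1
#' compactness(1, 6)                           # unit cube: 0.80600
#' @export
compactness <- function(volume, area) {
  if (any(!is.finite(volume)) || any(!is.finite(area)) ||
      any(volume <= 0) || any(area <= 0)) {
    stop("volume and area must be positive and finite")
  }
  (36 * pi * volume^2)^(1 / 3) / area
}

# Batched radial-extent query. ray_mat: m x n_rays (one row per query,
# rows may repeat a shape); U: m x 3 unit query directions. For each
# query the spherical triangle containing u is found (the face whose
# barycentric coordinates of u are all nonnegative; numerically, the face
# maximizing the smallest coordinate), and the three ray lengths are
# interpolated with the normalized coordinates. Continuous in u, exact at
# the stored directions, and exactly r for a constant-ray shape.
radial_extents <- function(ray_mat, U, dirs) {
  m <- nrow(U)
  stopifnot(nrow(ray_mat) == m, ncol(U) == 3)
  nf <- nrow(dirs$faces)
  best_min <- rep(-Inf, m)
  best_face <- integer(m)
  best_c <- matrix(0, m, 3)
  for (f in seq_len(nf)) {
    co <- U %*% dirs$face_inv[, , f]
    mn <- pmin(co[, 1], co[, 2], co[, 3])
    sel <- mn > best_min
    if (any(sel)) {
      best_min[sel] <- mn[sel]
      best_face[sel] <- f
      best_c[sel, ] <- co[sel, , drop = FALSE]
    }
  }
  w <- pmax(best_c, 0)
  w <- w / rowSums(w)
  fv <- dirs$faces[best_face, , drop = FALSE]
  idx <- seq_len(m)
  w[, 1] * ray_mat[cbind(idx, fv[, 1])] +
    w[, 2] * ray_mat[cbind(idx, fv[, 2])] +
    w[, 3] * ray_mat[cbind(idx, fv[, 3])]
}

#' Boundary distance of a star-convex shape along a direction
#'
#' Distance from the nucleus center to its boundary along a unit vector
#' `u`, by barycentric interpolation of the three ray lengths of the
#' spherical triangle containing `u`. Used by the border-to-border
#' distance (cytoplasm-thickness proxy) of the neighbor graph.
#'
#' @param rays Numeric vector of ray lengths (or a one-row matrix).
#' @param dirs A [direction_set()].
#' @param u Unit 3-vector, or a matrix of row vectors (one extent each).
#' @return Numeric vector of boundary distances (um).
#' @export
radial_extent <- function(rays, dirs, u) {
  stopifnot(inherits(dirs, "direction_set"))
  u <- rbind(u)
  nrm <- sqrt(rowSums(u^2))
  if (any(nrm < 1e-12)) stop("query direction must be a nonzero vector")
  u <- u / nrm
  rays <- rbind(c(rays))
  if (ncol(rays) != dirs$n_rays) stop("ray count does not match the direction set")
  rmat <- rays[rep(1, nrow(u)), , drop = FALSE]
  radial_extents(rmat, u, dirs)
}

#' Volume of the convex hull of a 3D point cloud
#'
#' Independent of the direction-set mesh: the hull facets are extracted
#' from the triangulation of the points themselves and the volume summed
#' from signed tetrahedra against the centroid. For ray endpoints in
#' convex position this equals [shape_metrics()]'s volume.
#'
#' @param pts n x 3 matrix of points (n >= 4, not all coplanar).
#' @return Hull volume.
#' @export
convex_hull_volume <- function(pts) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3, nrow(pts) >= 4)
  hull_of <- function(p) {
    res <- .delaunay3d_cpp(p, seq_len(nrow(p)))
    if (!isTRUE(res$ok)) return(NULL)
    res$hull
  }
  hull_valid <- function(p, h) {
    # every input point must lie on the inner side of every facet plane
    ctr <- colMeans(p)
    tol <- 1e-9 * max(apply(p, 2, function(v) diff(range(v))), 1)
    for (f in seq_len(nrow(h))) {
      a <- p[h[f, 1], ]; b <- p[h[f, 2], ]; c_ <- p[h[f, 3], ]
      nrm <- c((b[2] - a[2]) * (c_[3] - a[3]) - (b[3] - a[3]) * (c_[2] - a[2]),
               (b[3] - a[3]) * (c_[1] - a[1]) - (b[1] - a[1]) * (c_[3] - a[3]),
               (b[1] - a[1]) * (c_[2] - a[2]) - (b[2] - a[2]) * (c_[1] - a[1]))
      if (sum(nrm * (ctr - a)) > 0) nrm <- -nrm # point outward
      if (max(sweep(p, 2, a) %*% nrm) > tol * sqrt(sum(nrm^2))) return(FALSE)
    }
    TRUE
  }
  h <- hull_of(pts)
  if (is.null(h) || !hull_valid(pts, h)) {
    # coplanar/cospherical ties: break them with a tiny deterministic
    # jitter (volume perturbed by ~1e-7 relative)
    diam <- max(apply(pts, 2, function(v) diff(range(v))), 1)
    i <- seq_len(length(pts))
    pts <- pts + 1e-7 * diam * sin(3 * i + 1) * cos(7 * i)
    h <- hull_of(pts)
    if (is.null(h)) stop("degenerate point cloud (coplanar?)")
  }
  ctr <- colMeans(pts)
  a <- sweep(pts[h[, 1], , drop = FALSE], 2, ctr)
  b <- sweep(pts[h[, 2], , drop = FALSE], 2, ctr)
  c_ <- sweep(pts[h[, 3], , drop = FALSE], 2, ctr)
  dets <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  # the centroid is interior, so facet orientation is globally consistent
  abs(sum(dets)) / 6
}

#' Convert a labeled voxel mask to a star-convex shape
#'
#' Ingestion path for label-volume segmentations: the center is the
#' foreground centroid in physical micrometres (voxel centers at
#' `(index - 0.5) * spacing`), and each ray is the largest distance along
#' its direction still inside a foreground voxel: marched at steps of half
#' the smallest voxel spacing, refined by bisection to the exit boundary
#' of the last foreground voxel, and floored at half a voxel diagonal.
#'
#' @param mask 3D logical/numeric array indexed `[z, y, x]`.
#' @param spacing Length-3 positive numeric, voxel spacing in um for
#'   `(z, y, x)`.
#' @param dirs A [direction_set()].
#' @param image_id,nucleus_id Identifiers for the output row.
#' @return One-row shape table.
#' @export
voxels_to_shape <- function(mask, spacing, dirs, image_id = "img",
                            nucleus_id = 1L) {
  stopifnot(inherits(dirs, "direction_set"))
  if (length(dim(mask)) != 3) stop("mask must be a 3D array [z, y, x]")
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be three positive values (z, y, x), in um")
  }
  fg <- which(mask != 0, arr.ind = TRUE) # columns: z, y, x indices
  if (nrow(fg) == 0) stop("empty instance: mask has no foreground voxel")
  # physical coordinates (x, y, z) in um
  phys <- cbind((fg[, 3] - 0.5) * spacing[3],
                (fg[, 2] - 0.5) * spacing[2],
                (fg[, 1] - 0.5) * spacing[1])
  ctr <- colMeans(phys)
  step <- min(spacing) / 2
  dimz <- dim(mask)
  tmax <- sqrt(sum((dimz * spacing[c(1, 2, 3)])^2))
  tgrid <- seq(0, tmax, by = step)
  floor_val <- 0.5 * sqrt(sum(spacing^2))
  in_fg <- function(t, u) {
    p <- ctr + t * u # (x, y, z)
    iz <- floor(p[3] / spacing[1]) + 1
    iy <- floor(p[2] / spacing[2]) + 1
    ix <- floor(p[1] / spacing[3]) + 1
    iz >= 1 && iz <= dimz[1] && iy >= 1 && iy <= dimz[2] &&
      ix >= 1 && ix <= dimz[3] && mask[iz, iy, ix] != 0
  }
  rays <- vapply(seq_len(dirs$n_rays), function(k) {
    u <- dirs$directions[k, ]
    px <- ctr[1] + tgrid * u[1]
    py <- ctr[2] + tgrid * u[2]
    pz <- ctr[3] + tgrid * u[3]
    iz <- floor(pz / spacing[1]) + 1
    iy <- floor(py / spacing[2]) + 1
    ix <- floor(px / spacing[3]) + 1
    ok <- iz >= 1 & iz <= dimz[1] & iy >= 1 & iy <= dimz[2] &
      ix >= 1 & ix <= dimz[3]
    inside <- rep(FALSE, length(tgrid))
    inside[ok] <- mask[cbind(iz[ok], iy[ok], ix[ok])] != 0
    if (!any(inside)) return(floor_val)
    # refine from the last inside sample to the voxel exit boundary
    lo <- max(tgrid[inside])
    hi <- lo + step
    for (b in 1:12) {
      mid <- (lo + hi) / 2
      if (in_fg(mid, u)) lo <- mid else hi <- mid
    }
    lo
  }, numeric(1))
  rays <- pmax(rays, floor_val)
  shape_table(ctr, matrix(rays, 1), image_id = image_id,
              nucleus_id = nucleus_id)
}

#' Read a labeled multi-page TIFF volume into a shape table
#'
#' Pages are stacked as the z axis; pixel values are integer instance
#' labels (0 = background). Each label becomes one star-convex shape via
#' [voxels_to_shape()].
#'
#' @param path Path to the multi-page TIFF.
#' @param spacing Voxel spacing `(z, y, x)` in um.
#' @param dirs A [direction_set()].
#' @param image_id Identifier stored in the output.
#' @return Shape table with one row per label.
#' @export
read_label_volume <- function(path, spacing, dirs, image_id = "img") {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to read label volumes")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vol <- array(0L, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (z in seq_along(pages)) vol[z, , ] <- as.integer(round(pages[[z]]))
  labels <- sort(setdiff(unique(as.vector(vol)), 0L))
  if (length(labels) == 0) stop("label volume contains no instances")
  out <- lapply(labels, function(lb) {
    voxels_to_shape(vol == lb, spacing, dirs, image_id = image_id,
                    nucleus_id = lb)
  })
  dplyr::bind_rows(out)
}
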