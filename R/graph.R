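#' Build the Delaunay-derived neighbor graph of one image
#'
#' Nuclei centers are triangulated in 3D (Delaunay) and exactly those
#' Delaunay edges with center-to-center distance strictly below `cutoff`
#' are kept, following the convention that two epidermal cells are
#' neighbors when their nuclei are closer than 50 um. Nuclei with no kept
#' edge remain as isolated nodes. With fewer than 5 nuclei, or when the
#' centers are degenerate (all coplanar) even after jittering, the
#' complete graph filtered by the cutoff is used instead.
#'
#' A deterministic seeded jitter (triangulation only; all reported
#' distances use the unjittered coordinates) protects the triangulation
#' from collinear/coplanar/cospherical inputs.
#'
#' @param shapes Shape table of one image ([shape_table()]).
#' @param cutoff Edge cutoff on center distance, um (default 50).
#' @param jitter_amplitude Jitter amplitude, um (default 1e-4).
#' @param jitter_seed Seed for the jitter and insertion order.
#' @return An object of class `neighbor_graph`: list with `nodes`
#'   (tibble: `nucleus_id`, `degree`, `on_hull` — a convex-hull flag
#'   usable for border-cell sensitivity checks), `edges` (tibble:
#'   `id_a`, `id_b`, `d_center_um`, `d_border_um` — border distances are
#'   `NA` until [edge_geometry()] fills them) and `cutoff`.
#' @export
build_graph <- function(shapes, cutoff = 50, jitter_amplitude = 1e-4,
                        jitter_seed = 1L) {
  stopifnot(cutoff > 0, jitter_amplitude >= 0)
  ctr <- centers_matrix(shapes)
  n <- nrow(ctr)
  if (n == 0) stop("no nuclei in shape table")
  ids <- shapes$nucleus_id %||% seq_len(n)
  if (anyDuplicated(ids)) stop("duplicate nucleus_id in shape table")

  on_hull <- rep(NA, n)
  if (n == 1) {
    ep <- matrix(integer(0), 0, 2)
  } else if (n < 5) {
    ep <- t(utils::combn(n, 2))
  } else {
    res <- with_seed(jitter_seed, {
      jit <- matrix(runif(3 * n, -jitter_amplitude, jitter_amplitude), n, 3)
      .delaunay3d_cpp(ctr + jit, sample.int(n))
    })
    if (isTRUE(res$ok)) {
      ep <- res$edges
      on_hull <- seq_len(n) %in% unique(as.vector(res$hull))
    } else {
      # degenerate beyond repair by jitter: complete graph fallback
      ep <- t(utils::combn(n, 2))
    }
  }

  if (nrow(ep) > 0) {
    dvec <- sqrt(rowSums((ctr[ep[, 1], , drop = FALSE] -
                          ctr[ep[, 2], , drop = FALSE])^2))
    keep <- dvec < cutoff
    ep <- ep[keep, , drop = FALSE]
    dvec <- dvec[keep]
  } else {
    dvec <- numeric(0)
  }

  deg <- tabulate(as.vector(ep), nbins = n)
  edges <- tibble::tibble(
    id_a = ids[ep[, 1]], id_b = ids[ep[, 2]],
    d_center_um = dvec, d_border_um = NA_real_
  )
  structure(
    list(
      nodes = tibble::tibble(nucleus_id = ids, degree = deg,
                             on_hull = on_hull),
      edges = edges,
      cutoff = cutoff
    ),
    class = "neighbor_graph"
  )
}

#' Fill border-to-border distances on a neighbor graph
#'
#' For an edge (i, j) with unit direction `u` from center i to center j,
#' the border distance is `max(0, d_center - extent_i(u) - extent_j(-u))`
#' where the extents are the star-convex boundary distances along the
#' center line ([radial_extent()]). It proxies the cytoplasm thickness
#' between the two nuclei and is clamped at 0 when the surfaces overlap
#' along the center line. Coincident centers yield a zero distance with a
#' warning.
#'
#' @param graph A [build_graph()] result.
#' @param shapes The same image's shape table.
#' @param dirs A [direction_set()].
#' @return The graph with `d_border_um` filled.
#' @export
edge_geometry <- function(graph, shapes, dirs) {
  stopifnot(inherits(graph, "neighbor_graph"), inherits(dirs, "direction_set"))
  ids <- shapes$nucleus_id %||% seq_len(nrow(shapes))
  if (!all(c(graph$edges$id_a, graph$edges$id_b) %in% ids)) {
    stop("graph references nuclei absent from the shape table")
  }
  if (nrow(graph$edges) == 0) return(graph)
  ctr <- centers_matrix(shapes)
  rmat <- ray_matrix(shapes, dirs)
  ia <- match(graph$edges$id_a, ids)
  ib <- match(graph$edges$id_b, ids)
  dv <- ctr[ib, , drop = FALSE] - ctr[ia, , drop = FALSE]
  d <- graph$edges$d_center_um
  zero <- d <= 0
  if (any(zero)) {
    warning(sum(zero), " edge(s) with coincident centers; border distance set to 0")
  }
  u <- dv / ifelse(d > 0, d, 1)
  ext_a <- radial_extents(rmat[ia, , drop = FALSE], u, dirs)
  ext_b <- radial_extents(rmat[ib, , drop = FALSE], -u, dirs)
  db <- pmax(0, d - ext_a - ext_b)
  db[zero] <- 0
  graph$edges$d_border_um <- db
  graph
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("<neighbor_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (cutoff ", x$cutoff, " um)\n", sep = "")
  invisible(x)
}

#' Export the edge list of a neighbor graph as a tibble
#'
#' @param graph A `neighbor_graph`.
#' @param image_id Identifier column value to prepend.
#' @return Tibble `image_id`, `id_a`, `id_b`, `d_center_um`, `d_border_um`.
#' @export
edge_table <- function(graph, image_id = "img") {
  stopifnot(inherits(graph, "neighbor_graph"))
  dplyr::bind_cols(tibble::tibble(image_id = rep(image_id, nrow(graph$edges))),
                   graph$edges)
}
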