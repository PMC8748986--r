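# The 13 cell-level morphometric features, in their canonical order.
FEATURE_COLS <- c(
  "volume", "compactness", "volume_over_compactness", "nb_neighbours",
  "neighbor_dist", "border_dist", "border_over_neigh_distances",
  "neighbours_avg_volumes", "neighbours_avg_compactness",
  "neighbours_std_volumes", "neighbours_std_compactness",
  "volume_neigh_ratio", "compactness_neigh_ratio"
)

#' Names of the 13 cell-level features
#'
#' @return Character vector of feature column names, canonical order.
#' @export
feature_names <- function() FEATURE_COLS

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Compute the 13 cell-level morphometric features of one image
#'
#' Per nucleus: its own volume, compactness and their ratio; then, over
#' the incident edges of the neighbor graph, the neighbor count, mean
#' center and border distances, the mean per-edge border/center ratio
#' (bounded in \[0, 1\], a proxy for the fraction of the cell occupied by
#' cytoplasm), and the mean, population standard deviation and self-to-
#' neighborhood ratios of neighbor volumes and compactness. Neighbor-
#' dependent features are `NA` exactly for isolated nuclei (degree 0).
#'
#' @param shapes Shape table of one image.
#' @param graph Its [build_graph()] + [edge_geometry()] neighbor graph
#'   (border distances are filled automatically if missing).
#' @param dirs A [direction_set()].
#' @return A tibble with `image_id`, `nucleus_id`, the 13 feature columns
#'   and `n_missing` (count of missing neighbor-dependent fields).
#' @export
cell_features <- function(shapes, graph, dirs) {
  stopifnot(inherits(graph, "neighbor_graph"))
  ids <- shapes$nucleus_id %||% seq_len(nrow(shapes))
  if (!setequal(graph$nodes$nucleus_id, ids)) {
    stop("graph and shape table refer to different nuclei")
  }
  if (nrow(graph$edges) > 0 && anyNA(graph$edges$d_border_um)) {
    graph <- edge_geometry(graph, shapes, dirs)
  }
  sm <- shape_metrics(shapes, dirs)

  own <- sm |>
    dplyr::mutate(volume_over_compactness = .data$volume / .data$compactness) |>
    dplyr::select("image_id", "nucleus_id", "volume", "compactness",
                  "volume_over_compactness")

  e <- graph$edges
  if (nrow(e) > 0) {
    # undirected edges seen from both endpoints
    half <- dplyr::bind_rows(
      tibble::tibble(nucleus_id = e$id_a, nb = e$id_b,
                     d_center = e$d_center_um, d_border = e$d_border_um),
      tibble::tibble(nucleus_id = e$id_b, nb = e$id_a,
                     d_center = e$d_center_um, d_border = e$d_border_um)
    )
    half$ratio <- ifelse(half$d_center > 0, half$d_border / half$d_center, 0)
    half <- dplyr::left_join(
      half,
      sm |> dplyr::select(nb = "nucleus_id", nb_volume = "volume",
                          nb_compactness = "compactness"),
      by = "nb"
    )
    agg <- half |>
      dplyr::group_by(.data$nucleus_id) |>
      dplyr::summarise(
        nb_neighbours = dplyr::n(),
        neighbor_dist = mean(.data$d_center),
        border_dist = mean(.data$d_border),
        border_over_neigh_distances = mean(.data$ratio),
        neighbours_avg_volumes = mean(.data$nb_volume),
        neighbours_avg_compactness = mean(.data$nb_compactness),
        neighbours_std_volumes = pop_sd(.data$nb_volume),
        neighbours_std_compactness = pop_sd(.data$nb_compactness),
        .groups = "drop"
      )
  } else {
    agg <- tibble::tibble(
      nucleus_id = ids[0], nb_neighbours = integer(0),
      neighbor_dist = numeric(0), border_dist = numeric(0),
      border_over_neigh_distances = numeric(0),
      neighbours_avg_volumes = numeric(0),
      neighbours_avg_compactness = numeric(0),
      neighbours_std_volumes = numeric(0),
      neighbours_std_compactness = numeric(0)
    )
  }

  out <- own |>
    dplyr::left_join(agg, by = "nucleus_id") |>
    dplyr::mutate(
      nb_neighbours = dplyr::coalesce(.data$nb_neighbours, 0L),
      volume_neigh_ratio = .data$volume / .data$neighbours_avg_volumes,
      compactness_neigh_ratio = .data$compactness / .data$neighbours_avg_compactness
    ) |>
    dplyr::select(dplyr::all_of(c("image_id", "nucleus_id", FEATURE_COLS)))
  out$n_missing <- rowSums(is.na(out[FEATURE_COLS]))
  out
}

#' Image-level aggregates of the cell features
#'
#' Cell density (nuclei per mm^2 of en-face area, the x-y field of view,
#' which corresponds to the imaged skin surface), means and standard
#' deviations of volume and compactness over all nuclei, and means of the
#' neighbor-distance features over nuclei with at least one neighbor.
#'
#' @param features A [cell_features()] table (one or more images).
#' @param fov_x_mm,fov_y_mm En-face field-of-view extents, mm.
#' @return One-row-per-image tibble of image metrics.
#' @export
image_metrics <- function(features, fov_x_mm, fov_y_mm) {
  stopifnot(fov_x_mm > 0, fov_y_mm > 0)
  if (nrow(features) == 0) stop("empty feature table")
  features |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      cell_density = dplyr::n() / (fov_x_mm * fov_y_mm),
      mean_volume = mean(.data$volume),
      std_volume = sd(.data$volume),
      mean_compactness = mean(.data$compactness),
      std_compactness = sd(.data$compactness),
      mean_neighbor_dist = mean(.data$neighbor_dist, na.rm = TRUE),
      mean_border_dist = mean(.data$border_dist, na.rm = TRUE),
      mean_border_over_center_ratio =
        mean(.data$border_over_neigh_distances, na.rm = TRUE),
      .groups = "drop"
    )
}

# Image-level metrics tested against diagnosis in the Fig-2-style t-test
# panel (density is lower in pathological skin; the others larger/smaller
# per their sign there).
IMAGE_METRIC_COLS <- c(
  "cell_density", "mean_volume", "std_volume", "mean_compactness",
  "std_compactness", "mean_neighbor_dist", "mean_border_dist",
  "mean_border_over_center_ratio"
)
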