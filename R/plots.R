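#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Box plot of image atypia scores by diagnosis
#'
#' The per-image mean atypia score, grouped by diagnosis class ordered by
#' clinical severity, for one result or a wide [image_score_table()].
#'
#' @param object An `atypia_result` or a wide image-score tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot atypia_result
#' @export
autoplot.atypia_result <- function(object, ...) {
  plot_image_scores(image_score_table(list(object)))
}

#' @rdname autoplot.atypia_result
#' @param scores Wide image-score tibble (`image_id`, `diagnosis`, one
#'   column per method).
#' @export
plot_image_scores <- function(scores, ...) {
  long <- scores |>
    tidyr::pivot_longer(
      cols = -dplyr::any_of(c("image_id", "diagnosis", "fold",
                              "n_cells_scored")),
      names_to = "method", values_to = "score"
    ) |>
    dplyr::mutate(diagnosis = factor(.data$diagnosis,
                                     levels = DIAGNOSIS_LEVELS))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$diagnosis, y = .data$score,
                                     fill = .data$diagnosis)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = NULL, y = "mean image atypia score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Box plots of image metrics by group, annotated with t statistics
#'
#' One panel per image-level metric, healthy vs pathological, with the
#' pooled-variance t statistic in the panel label (positive = larger in
#' pathological skin).
#'
#' @param metrics An [image_metrics()] table.
#' @param manifest Tibble `image_id`, `diagnosis`.
#' @return A ggplot.
#' @export
plot_image_metrics <- function(metrics, manifest) {
  tt <- image_metric_ttests(metrics, manifest)
  lab <- setNames(sprintf("%s (t = %.2f)", tt$metric, tt$statistic),
                  tt$metric)
  d <- metrics |>
    dplyr::left_join(manifest |> dplyr::select("image_id", "diagnosis"),
                     by = "image_id") |>
    dplyr::mutate(group = ifelse(is_pathological(.data$diagnosis),
                                 "pathological", "healthy")) |>
    tidyr::pivot_longer(dplyr::all_of(IMAGE_METRIC_COLS),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = factor(.data$metric, levels = IMAGE_METRIC_COLS))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$value,
                                  fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y",
                        labeller = ggplot2::as_labeller(lab)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
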