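#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an atypia result into its image-score table
#'
#' @param x An [cv_scores()] result.
#' @param level `"image"` (default) or `"cell"`.
#' @param ... Unused.
#' @return A tibble of scores at the requested level.
#' @method tidy atypia_result
#' @export
tidy.atypia_result <- function(x, level = c("image", "cell"), ...) {
  level <- match.arg(level)
  out <- if (level == "image") x$image_scores else x$cell_scores
  dplyr::mutate(out, method = x$method, .before = 1)
}

#' One-row summary of an atypia result
#'
#' @param x An [cv_scores()] result.
#' @param ... Unused.
#' @return Tibble with method, cohort sizes and the healthy-vs-
#'   pathological image-level AUC.
#' @method glance atypia_result
#' @export
glance.atypia_result <- function(x, ...) {
  d <- x$image_scores
  tibble::tibble(
    method = x$method,
    n_images = nrow(d),
    n_cells_scored = nrow(x$cell_scores),
    n_excluded_degree0 = x$metadata$n_excluded_degree0,
    k = x$k,
    auc_healthy_vs_pathological =
      auc_mw(d$score, is_pathological(d$diagnosis))
  )
}

#' Tidy a fitted logistic atypia model
#'
#' @param x A [fit_logistic()] model.
#' @param ... Unused.
#' @return Tibble `term`, `estimate` (coefficients on the z-normalized
#'   scale).
#' @method tidy logistic_model
#' @export
tidy.logistic_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' Tidy rule thresholds
#'
#' @param x A [rule_thresholds()] object.
#' @param ... Unused.
#' @return One-row tibble of the three thresholds and `min_criteria`.
#' @method tidy rule_thresholds
#' @export
tidy.rule_thresholds <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}
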