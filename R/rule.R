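#' Rule-based atypia thresholds
#'
#' The rule flags a nucleus as a potential atypia when it is unusually
#' large (volume above `volume_max`), unusually flat (compactness below
#' `compactness_min`) or surrounded by unusually large neighbors
#' (`neighbours_avg_volumes` above `neighbour_volume_max`); a cell is
#' atypical when it meets at least `min_criteria` of the three. The
#' defaults are the published reference values, each the 10%-tail
#' quantile of a large clinical cohort: 280 um^3 (2.8e-7 mm^3), 0.592 and
#' 156 um^3 (1.56e-7 mm^3).
#'
#' @param volume_max Volume threshold, um^3.
#' @param compactness_min Compactness threshold (dimensionless).
#' @param neighbour_volume_max Neighborhood mean-volume threshold, um^3.
#' @param min_criteria Criteria required to flag a cell (1-3, default 2).
#' @return An object of class `rule_thresholds`.
#' @export
rule_thresholds <- function(volume_max = 280, compactness_min = 0.592,
                            neighbour_volume_max = 156, min_criteria = 2) {
  stopifnot(volume_max > 0, compactness_min > 0, neighbour_volume_max > 0,
            min_criteria >= 1, min_criteria <= 3)
  structure(
    list(volume_max = volume_max, compactness_min = compactness_min,
         neighbour_volume_max = neighbour_volume_max,
         min_criteria = as.integer(min_criteria)),
    class = "rule_thresholds"
  )
}

#' @export
print.rule_thresholds <- function(x, ...) {
  cat("<rule_thresholds> volume >", x$volume_max, "um^3 | compactness <",
      x$compactness_min, "| neighbour volumes >", x$neighbour_volume_max,
      "um^3 | >=", x$min_criteria, "criteria\n")
  invisible(x)
}

#' Calibrate the rule thresholds on a reference cohort
#'
#' Each threshold is set so that a `tail_fraction` of the reference nuclei
#' fall in the flagged tail: `volume_max` is the (1 - tail) quantile of
#' volume, `compactness_min` the tail quantile of compactness, and
#' `neighbour_volume_max` the (1 - tail) quantile of the neighborhood
#' mean volume (linear-interpolation quantiles).
#'
#' @param reference A [cell_features()] table.
#' @param tail_fraction Flagged tail per criterion (default 0.10).
#' @param min_criteria Passed through to [rule_thresholds()].
#' @return A `rule_thresholds` object.
#' @export
calibrate_rule <- function(reference, tail_fraction = 0.1, min_criteria = 2) {
  if (is.null(reference) || nrow(reference) == 0) {
    stop("cannot calibrate rule thresholds on an empty reference")
  }
  stopifnot(tail_fraction > 0, tail_fraction < 1)
  vq <- quantile(reference$volume, 1 - tail_fraction, names = FALSE)
  cq <- quantile(reference$compactness, tail_fraction, names = FALSE)
  nav <- reference$neighbours_avg_volumes
  nav <- nav[!is.na(nav)]
  if (length(nav) == 0) {
    stop("no nucleus with neighbors in the reference; cannot calibrate criterion 3")
  }
  nq <- quantile(nav, 1 - tail_fraction, names = FALSE)
  for (nm in c("volume", "compactness")) {
    if (length(unique(reference[[nm]])) == 1) {
      warning("degenerate calibration: constant ", nm,
              " in reference (all nuclei sit at the threshold)")
    }
  }
  rule_thresholds(vq, cq, nq, min_criteria = min_criteria)
}

#' Score cells with the rule-based atypia definition
#'
#' Evaluates the three criteria and flags each cell atypical (score 1)
#' when at least `min_criteria` are met simultaneously. A missing
#' neighborhood volume (isolated nucleus) leaves criterion 3 unmet.
#'
#' @param features A [cell_features()] table.
#' @param thresholds A [rule_thresholds()] object.
#' @return The identifier columns plus `criterion_volume`,
#'   `criterion_compactness`, `criterion_neighbours`, `n_met` and binary
#'   `score`.
#' @export
score_rule <- function(features, thresholds = rule_thresholds()) {
  stopifnot(inherits(thresholds, "rule_thresholds"))
  c1 <- features$volume > thresholds$volume_max
  c2 <- features$compactness < thresholds$compactness_min
  c3 <- !is.na(features$neighbours_avg_volumes) &
    features$neighbours_avg_volumes > thresholds$neighbour_volume_max
  n_met <- c1 + c2 + c3
  tibble::tibble(
    image_id = features$image_id,
    nucleus_id = features$nucleus_id,
    criterion_volume = c1,
    criterion_compactness = c2,
    criterion_neighbours = c3,
    n_met = as.integer(n_met),
    score = as.numeric(n_met >= thresholds$min_criteria)
  )
}
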