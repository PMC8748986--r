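#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney AUC with midrank tie handling: the probability that a
#' random positive (pathological) image scores above a random negative
#' (healthy) one, ties counting one half.
#'
#' @param scores Numeric scores.
#' @param positive Logical (or 0/1) vector: `TRUE` for the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(scores, positive) {
  positive <- as.logical(positive)
  if (length(scores) != length(positive) || anyNA(scores) || anyNA(positive)) {
    stop("scores and positive must be complete vectors of equal length")
  }
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute an AUC")
  r <- rank(scores) # midranks
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# the three diagnosis subsets evaluated at image level
SUBSETS <- list(
  healthy_vs_pathological = c("subclinical_ak", "ak", "bowen"),
  healthy_vs_ak_bowen = c("ak", "bowen"),
  healthy_vs_subclinical_ak = "subclinical_ak"
)

#' Evaluate image scores against diagnosis labels on the standard subsets
#'
#' For each diagnosis subset (healthy vs all pathological, healthy vs
#' AK + Bowen, healthy vs subclinical AK) and each score column, computes
#' the image-level AUC (pathological positive) and, optionally, the
#' Pearson correlation of the method's scores with a reference method's
#' on the same subset.
#'
#' @param image_scores Tibble with `image_id`, `diagnosis` and one or
#'   more numeric score columns (see [image_score_table()]).
#' @param reference Optional name of a score column correlations are
#'   computed against (e.g. `"gbt"`).
#' @return Tidy tibble: `subset`, `method`, `n`, `auc`, and when a
#'   reference is given `pearson_r`, `pearson_p` (NA for the reference
#'   itself).
#' @export
evaluation_report <- function(image_scores, reference = NULL) {
  meth <- setdiff(names(image_scores),
                  c("image_id", "diagnosis", "fold", "n_cells_scored"))
  meth <- meth[vapply(image_scores[meth], is.numeric, logical(1))]
  if (length(meth) == 0) stop("no numeric score columns found")
  if (!is.null(reference) && !reference %in% meth) {
    stop("reference method '", reference, "' is not a score column")
  }
  rows <- list()
  for (sub in names(SUBSETS)) {
    keep <- image_scores$diagnosis %in% c("healthy", SUBSETS[[sub]])
    d <- image_scores[keep, , drop = FALSE]
    pos <- is_pathological(d$diagnosis)
    if (!any(pos) || all(pos)) next # subset absent from this cohort
    for (m in meth) {
      r <- tibble::tibble(subset = sub, method = m, n = nrow(d),
                          auc = auc_mw(d[[m]], pos))
      if (!is.null(reference)) {
        if (m == reference) {
          r$pearson_r <- NA_real_; r$pearson_p <- NA_real_
        } else {
          ct <- pearson(d[[m]], d[[reference]])
          r$pearson_r <- ct$estimate; r$pearson_p <- ct$p_value
        }
      }
      rows[[length(rows) + 1]] <- r
    }
  }
  dplyr::bind_rows(rows)
}

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson correlation; the p-value comes from the exact
#' t-transform with n - 2 degrees of freedom.
#'
#' @param a,b Paired numeric vectors (>= 3 complete pairs, both with
#'   nonzero variance).
#' @return One-row tibble `estimate`, `statistic`, `p_value`, `n`.
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired")
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("need at least 3 paired values")
  if (sd(a) == 0 || sd(b) == 0) {
    stop("undefined correlation: zero variance in at least one vector")
  }
  ct <- cor.test(a, b, method = "pearson")
  tibble::tibble(estimate = unname(ct$estimate),
                 statistic = unname(ct$statistic),
                 p_value = ct$p.value, n = length(a))
}

#' Two-sample t-test comparing pathological and healthy groups
#'
#' Student's pooled-variance (equal-variance) two-sample t-test, two
#' sided. The sign convention puts the pathological group first, so a
#' positive statistic means larger values in pathological skin.
#'
#' @param pathological,healthy Numeric vectors (>= 2 values each).
#' @param var_equal Pooled variance (default `TRUE`); set `FALSE` for the
#'   Welch variant.
#' @return One-row tibble `statistic`, `p_value`, `df`,
#'   `mean_pathological`, `mean_healthy`.
#' @export
two_sample_t <- function(pathological, healthy, var_equal = TRUE) {
  pathological <- pathological[!is.na(pathological)]
  healthy <- healthy[!is.na(healthy)]
  if (length(pathological) < 2 || length(healthy) < 2) {
    stop("both groups need at least 2 values")
  }
  if (sd(pathological) == 0 && sd(healthy) == 0) {
    if (mean(pathological) == mean(healthy)) {
      return(tibble::tibble(statistic = 0, p_value = 1,
                            df = length(pathological) + length(healthy) - 2,
                            mean_pathological = mean(pathological),
                            mean_healthy = mean(healthy)))
    }
    stop("undefined statistic: zero variance in both groups")
  }
  tt <- t.test(pathological, healthy, var.equal = var_equal)
  tibble::tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter),
                 mean_pathological = mean(pathological),
                 mean_healthy = mean(healthy))
}

#' Fig-2-style t-tests of the image metrics
#'
#' One pooled-variance t-test per image metric, pathological minus
#' healthy sign convention.
#'
#' @param metrics An [image_metrics()] table.
#' @param manifest Tibble `image_id`, `diagnosis`.
#' @return Tibble `metric`, `statistic`, `p_value`, group means.
#' @export
image_metric_ttests <- function(metrics, manifest) {
  d <- dplyr::left_join(metrics,
                        manifest |> dplyr::select("image_id", "diagnosis"),
                        by = "image_id")
  patho <- is_pathological(d$diagnosis)
  dplyr::bind_rows(lapply(IMAGE_METRIC_COLS, function(m) {
    dplyr::bind_cols(tibble::tibble(metric = m),
                     two_sample_t(d[[m]][patho], d[[m]][!patho]))
  }))
}

#' Reader-study consensus score per image
#'
#' Each reader grades six criteria (shape, size and spatial spread of
#' atypical nuclei, on horizontal and vertical views) on a 0-4 scale; the
#' per-reader score is the sum over the six criteria normalized by the
#' maximum of 24, and the consensus is the mean of the readers'
#' normalized scores.
#'
#' @param sheet Tibble `image_id`, `reader_id` and six integer criterion
#'   columns (values 0-4); every (image, reader) pair must be complete.
#' @param criteria Names of the six criterion columns; defaults to all
#'   columns except the identifiers.
#' @return Tibble `image_id`, `consensus` in \[0, 1\], plus one
#'   `reader_<id>` column per reader.
#' @export
reader_consensus <- function(sheet, criteria = NULL) {
  criteria <- criteria %||% setdiff(names(sheet), c("image_id", "reader_id"))
  if (length(criteria) != 6) {
    stop("expected exactly 6 criterion columns, got ", length(criteria))
  }
  vals <- as.matrix(sheet[criteria])
  if (anyNA(vals)) stop("incomplete sheet: missing criterion scores")
  if (any(vals != round(vals)) || any(vals < 0) || any(vals > 4)) {
    stop("criterion scores must be integers in 0..4")
  }
  per_reader <- sheet |>
    dplyr::mutate(normalized = rowSums(dplyr::across(dplyr::all_of(criteria))) / 24) |>
    dplyr::select("image_id", "reader_id", "normalized")
  counts <- table(per_reader$image_id, per_reader$reader_id)
  if (any(counts != 1)) {
    stop("incomplete sheet: every reader must score every image exactly once")
  }
  wide <- per_reader |>
    tidyr::pivot_wider(names_from = "reader_id", values_from = "normalized",
                       names_prefix = "reader_")
  wide$consensus <- rowMeans(wide[setdiff(names(wide), "image_id")])
  dplyr::select(wide, "image_id", "consensus", dplyr::everything())
}
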