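ATYPIA_METHODS <- c("rule", "iforest", "logistic", "gbt")

#' Cross-validated per-cell atypia scores and image-level aggregation
#'
#' Runs one atypia-scoring method under image-level stratified k-fold
#' cross-validation: for each fold, the model is fit (or the rule
#' calibrated) on the cells of the other folds and the held-out cells are
#' scored, so every cell is scored exactly once by a model that never saw
#' its image. The image score is the plain mean of its cells' scores, no
#' thresholding.
#'
#' Isolated (degree-0) cells have missing neighbor features: they are
#' excluded from machine-learning training and scoring (their count is
#' recorded in the result metadata), while the rule scores them with
#' criterion 3 unmet. One master `seed` derives the fold, forest and
#' boosting seeds.
#'
#' @param features A [cell_features()] table for the whole cohort.
#' @param manifest Tibble `image_id`, `diagnosis` (one row per image).
#' @param method One of `"rule"`, `"iforest"`, `"logistic"`, `"gbt"`.
#' @param k Fold count (default 5).
#' @param seed Master seed.
#' @param thresholds Rule mode: `"calibrated"` recalibrates the 10%-tail
#'   thresholds on each training split (the definition of the published
#'   values), `"fixed"` applies `fixed_thresholds` everywhere.
#' @param tail_fraction Tail for rule recalibration (default 0.10).
#' @param fixed_thresholds A [rule_thresholds()] object for
#'   `thresholds = "fixed"`.
#' @return An object of class `atypia_result`: `cell_scores` (tibble
#'   `image_id`, `nucleus_id`, `fold`, `score`), `image_scores` (tibble
#'   `image_id`, `diagnosis`, `fold`, `n_cells_scored`, `score`), the
#'   fold assignment, and metadata.
#' @export
cv_scores <- function(features, manifest,
                      method = c("rule", "iforest", "logistic", "gbt"),
                      k = 5, seed = 1L,
                      thresholds = c("calibrated", "fixed"),
                      tail_fraction = 0.1,
                      fixed_thresholds = rule_thresholds()) {
  method <- match.arg(method)
  thresholds <- match.arg(thresholds)
  seed <- as.integer(seed)
  fold_seed <- seed
  iforest_seed <- seed + 1L
  gbt_seed <- seed + 2L

  folds <- stratified_folds(manifest, k = k, seed = fold_seed)
  feats <- dplyr::left_join(features, folds, by = "image_id")
  if (anyNA(feats$fold)) stop("feature table references images absent from the manifest")

  complete <- feats$n_missing == 0
  n_excluded <- sum(!complete)

  score_fold <- function(f) {
    test <- feats[feats$fold == f, , drop = FALSE]
    train <- feats[feats$fold != f, , drop = FALSE]
    if (method == "rule") {
      thr <- if (thresholds == "fixed") fixed_thresholds
             else calibrate_rule(train, tail_fraction = tail_fraction)
      sc <- score_rule(test, thr)
      return(tibble::tibble(image_id = test$image_id,
                            nucleus_id = test$nucleus_id,
                            fold = f, score = sc$score))
    }
    tr <- train[train$n_missing == 0, , drop = FALSE]
    te <- test[test$n_missing == 0, , drop = FALSE]
    xtr <- as.matrix(tr[FEATURE_COLS])
    xte <- as.matrix(te[FEATURE_COLS])
    sc <- switch(method,
      iforest = {
        fit <- fit_isolation_forest(xtr, seed = iforest_seed)
        raw_tr <- predict(fit, xtr)
        lo <- min(raw_tr); hi <- max(raw_tr)
        if (hi <= lo) stop("degenerate isolation-forest scores in fold ", f)
        pmin(1, pmax(0, (predict(fit, xte) - lo) / (hi - lo)))
      },
      logistic = {
        ml <- weak_labels(tr, manifest)
        if (length(unique(ml$weak_label)) < 2) {
          stop("fold ", f, ": training images are single-class; ",
               "weak supervision needs both healthy and pathological images")
        }
        predict(fit_logistic(xtr, ml$weak_label), xte)
      },
      gbt = {
        ml <- weak_labels(tr, manifest)
        if (length(unique(ml$weak_label)) < 2) {
          stop("fold ", f, ": training images are single-class; ",
               "weak supervision needs both healthy and pathological images")
        }
        predict(fit_gbt(xtr, ml$weak_label, seed = gbt_seed), xte)
      }
    )
    tibble::tibble(image_id = te$image_id, nucleus_id = te$nucleus_id,
                   fold = f, score = as.numeric(sc))
  }

  cell_scores <- dplyr::bind_rows(lapply(sort(unique(folds$fold)), score_fold))

  image_scores <- cell_scores |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(n_cells_scored = dplyr::n(),
                     score = mean(.data$score), .groups = "drop")
  image_scores <- manifest |>
    dplyr::select("image_id", "diagnosis") |>
    dplyr::left_join(folds, by = "image_id") |>
    dplyr::left_join(image_scores, by = "image_id")

  structure(
    list(method = method, k = k, seed = seed,
         cell_scores = cell_scores, image_scores = image_scores,
         folds = folds,
         metadata = list(
           n_cells = nrow(feats), n_excluded_degree0 = n_excluded,
           thresholds_mode = if (method == "rule") thresholds else NA,
           tail_fraction = if (method == "rule") tail_fraction else NA,
           fold_seed = fold_seed, iforest_seed = iforest_seed,
           gbt_seed = gbt_seed)),
    class = "atypia_result"
  )
}

#' @export
print.atypia_result <- function(x, ...) {
  cat("<atypia_result> method:", x$method, "|", x$k, "folds | ",
      nrow(x$image_scores), "images,", nrow(x$cell_scores), "cells scored\n")
  invisible(x)
}

#' Run several scoring methods on the same cohort
#'
#' @param features,manifest As in [cv_scores()].
#' @param methods Character vector of methods to run.
#' @param ... Passed to [cv_scores()].
#' @return Named list of `atypia_result` objects.
#' @export
score_cohort <- function(features, manifest, methods = ATYPIA_METHODS, ...) {
  stopifnot(all(methods %in% ATYPIA_METHODS))
  setNames(lapply(methods, function(m) {
    cv_scores(features, manifest, method = m, ...)
  }), methods)
}

#' Image-score table of one or more atypia results, wide by method
#'
#' @param results An `atypia_result` or a named list of them.
#' @return Tibble `image_id`, `diagnosis`, `fold`, one score column per
#'   method.
#' @export
image_score_table <- function(results) {
  if (inherits(results, "atypia_result")) results <- list(results)
  if (is.null(names(results)) || any(names(results) == "")) {
    names(results) <- vapply(results, function(r) r$method, character(1))
  }
  out <- NULL
  for (nm in names(results)) {
    sc <- results[[nm]]$image_scores |>
      dplyr::select("image_id", "diagnosis", "fold", !!nm := "score")
    out <- if (is.null(out)) sc
           else dplyr::left_join(out, sc |> dplyr::select(-"diagnosis", -"fold"),
                                 by = "image_id")
  }
  out
}
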