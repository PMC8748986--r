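#' Weak per-cell labels from image-level diagnoses
#'
#' The weak-supervision paradigm: every nucleus of a pathological image
#' (subclinical AK, AK, Bowen) is labeled atypical (1) and every nucleus
#' of a healthy image healthy (0). Labels are noisy per cell but constant
#' within an image.
#'
#' @param features A [cell_features()] table (needs `image_id`).
#' @param manifest Tibble with `image_id` and `diagnosis`.
#' @return `features` with a `weak_label` column (0/1).
#' @export
weak_labels <- function(features, manifest) {
  if (!all(features$image_id %in% manifest$image_id)) {
    stop("feature table references images absent from the manifest")
  }
  lab <- tibble::tibble(
    image_id = manifest$image_id,
    weak_label = as.numeric(is_pathological(manifest$diagnosis))
  )
  dplyr::left_join(features, lab, by = "image_id")
}

#' Stratified image-level fold assignment
#'
#' Images are split into `k` folds of near-equal size such that each fold
#' holds a similar proportion of healthy and pathological images (within
#' one image of the global proportion). All cells of an image share its
#' fold. Deterministic for a given seed.
#'
#' @param manifest Tibble with `image_id` and `diagnosis`.
#' @param k Fold count (default 5).
#' @param seed Seed for the within-class shuffles.
#' @return Tibble `image_id`, `fold` (1..k).
#' @export
stratified_folds <- function(manifest, k = 5, seed = 1L) {
  patho <- is_pathological(manifest$diagnosis)
  n_min <- min(sum(patho), sum(!patho))
  if (k < 2) stop("k must be at least 2")
  if (k > n_min) {
    stop("k = ", k, " exceeds the minority class size (", n_min, " images)")
  }
  with_seed(seed, {
    fold <- integer(nrow(manifest))
    fill <- integer(k) # images assigned so far, per fold
    for (cls in list(which(!patho), which(patho))) {
      ord <- sample(cls)
      sizes <- rep(length(ord) %/% k, k) +
        (seq_len(k) <= length(ord) %% k)
      # largest chunks go to the currently least-filled folds
      target <- order(fill, seq_len(k))[order(-sizes)]
      stops <- cumsum(sizes[order(-sizes)])
      starts <- c(1, head(stops, -1) + 1)
      for (i in seq_len(k)) {
        if (starts[i] > stops[i]) next
        fold[ord[starts[i]:stops[i]]] <- target[i]
      }
      fill <- fill + tabulate(fold[cls], nbins = k)
    }
    tibble::tibble(image_id = manifest$image_id, fold = fold)
  })
}

#' Fit the weakly-supervised logistic atypia model
#'
#' Features are z-normalized with training statistics (mean 0, SD 1 per
#' column), then a maximum-likelihood logistic regression
#' `p = sigmoid(b0 + b1 x1 + ... + bn xn)` is fit on the weak labels.
#' Prediction applies the training normalization to unseen cells.
#'
#' @param x Feature matrix or data frame (no missing values).
#' @param y Binary labels (0/1), both classes present.
#' @return An object of class `logistic_model` with coefficients,
#'   normalization statistics and the effective regularization recorded
#'   in `$regularization`.
#' @export
fit_logistic <- function(x, y) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("logistic input must have no missing values")
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  ctr <- colMeans(x)
  scl <- apply(x, 2, pop_sd)
  if (any(scl <= 0)) {
    stop("constant feature(s) in training data: ",
         paste(colnames(x)[scl <= 0], collapse = ", "))
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  df <- as.data.frame(z)
  df$.y <- y
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  structure(
    list(coefficients = stats::coef(fit), center = ctr, scale = scl,
         converged = fit$converged,
         regularization = "none (unpenalized maximum likelihood)"),
    class = "logistic_model"
  )
}

#' @export
predict.logistic_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  eta <- object$coefficients[1] + as.vector(z %*% object$coefficients[-1])
  1 / (1 + exp(-eta))
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("<logistic_model> ", length(x$coefficients) - 1,
      " features, z-normalized; regularization: ", x$regularization, "\n",
      sep = "")
  invisible(x)
}

#' Fit the weakly-supervised gradient-boosted-trees atypia model
#'
#' Gradient-boosted trees on the weak labels, untuned: 200 boosting
#' rounds (no early stopping), maximum depth 5, row subsample 0.5, fixed
#' seed, single-threaded for bit reproducibility.
#'
#' @param x Feature matrix or data frame (no missing values).
#' @param y Binary labels (0/1), both classes present.
#' @param seed Seed for the boosting subsampling.
#' @param nrounds,max_depth,subsample Boosting hyperparameters.
#' @return An object of class `gbt_model`.
#' @export
fit_gbt <- function(x, y, seed = 1L, nrounds = 200, max_depth = 5,
                    subsample = 0.5) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("gbt input must have no missing values")
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  subsample = subsample, nthread = 1,
                  seed = as.integer(seed)),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
  structure(list(booster = booster, n_features = ncol(x)),
            class = "gbt_model")
}

#' @export
predict.gbt_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  predict(object$booster, xgboost::xgb.DMatrix(x, nthread = 1))
}

#' @export
print.gbt_model <- function(x, ...) {
  cat("<gbt_model> gradient-boosted trees,", x$n_features, "features\n")
  invisible(x)
}
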