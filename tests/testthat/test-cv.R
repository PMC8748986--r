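# a small deterministic cohort shared by the CV contract tests
cv_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    dirs <- shared_dirs()
    pres <- tissue_presets(tissue_params(fov_x_mm = 0.15, fov_y_mm = 0.15))
    coh <- simulate_cohort(c(healthy = 6, ak = 6), presets = pres,
                           seed = 314, dirs = dirs)
    fe <- dplyr::bind_rows(lapply(split(coh$shapes, coh$shapes$image_id),
      function(s) {
        g <- edge_geometry(build_graph(s), s, dirs)
        cell_features(s, g, dirs)
      }))
    cache <<- list(features = fe, manifest = coh$manifest)
    cache
  }
})

test_that("rule scoring with fixed thresholds is identical with and without CV", {
  fx <- cv_fixture()
  thr <- rule_thresholds()
  res <- cv_scores(fx$features, fx$manifest, method = "rule", k = 3,
                   seed = 4, thresholds = "fixed", fixed_thresholds = thr)
  direct <- score_rule(fx$features, thr)
  joined <- dplyr::left_join(res$cell_scores, direct,
                             by = c("image_id", "nucleus_id"))
  expect_equal(joined$score.x, joined$score.y)
  # rule image score is the fraction of flagged cells
  img <- dplyr::summarise(dplyr::group_by(direct, image_id),
                          frac = mean(score))
  cmp <- dplyr::left_join(res$image_scores, img, by = "image_id")
  expect_equal(cmp$score, cmp$frac)
})

test_that("every cell is scored exactly once by an out-of-fold model", {
  fx <- cv_fixture()
  for (m in c("iforest", "logistic")) {
    res <- cv_scores(fx$features, fx$manifest, method = m, k = 3, seed = 4)
    complete <- fx$features[fx$features$n_missing == 0, ]
    expect_equal(nrow(res$cell_scores), nrow(complete))
    expect_false(anyDuplicated(
      paste(res$cell_scores$image_id, res$cell_scores$nucleus_id)) > 0)
    expect_true(all(res$cell_scores$score >= 0 & res$cell_scores$score <= 1))
    # cells carry the fold of their image
    chk <- dplyr::distinct(res$cell_scores, image_id, fold)
    expect_identical(nrow(chk), nrow(fx$manifest))
  }
})

test_that("held-out cells do not influence the model that scores their fold-mates", {
  fx <- cv_fixture()
  res <- cv_scores(fx$features, fx$manifest, method = "logistic", k = 3,
                   seed = 11)
  # drop one held-out image entirely and rescore with the same folds:
  # scores of the other images in that fold must be unchanged
  drop_img <- res$folds$image_id[1]
  fold_of <- res$folds$fold[1]
  fe2 <- fx$features[fx$features$image_id != drop_img, ]
  # refit the fold model manually on the identical training split
  train <- dplyr::left_join(fx$features, res$folds, by = "image_id")
  train <- train[train$fold != fold_of & train$n_missing == 0, ]
  lab <- weak_labels(train, fx$manifest)
  fit <- fit_logistic(as.matrix(train[feature_names()]), lab$weak_label)
  mates <- dplyr::left_join(fe2, res$folds, by = "image_id")
  mates <- mates[mates$fold == fold_of & mates$n_missing == 0, ]
  p <- predict(fit, as.matrix(mates[feature_names()]))
  ref <- res$cell_scores[match(paste(mates$image_id, mates$nucleus_id),
                               paste(res$cell_scores$image_id,
                                     res$cell_scores$nucleus_id)), ]
  expect_equal(unname(p), ref$score, tolerance = 1e-12)
})

test_that("method image scores are positively correlated on a graded cohort", {
  fx <- cv_fixture()
  res <- score_cohort(fx$features, fx$manifest,
                      methods = c("rule", "logistic", "gbt"), k = 3, seed = 21)
  wide <- image_score_table(res)
  pairs <- utils::combn(c("rule", "logistic", "gbt"), 2)
  for (j in seq_len(ncol(pairs))) {
    expect_gt(cor(wide[[pairs[1, j]]], wide[[pairs[2, j]]]), 0)
  }
  # glance/tidy contracts
  gl <- generics::glance(res$logistic)
  expect_equal(gl$n_images, 12)
  expect_true(gl$auc_healthy_vs_pathological >= 0 &&
                gl$auc_healthy_vs_pathological <= 1)
  td <- generics::tidy(res$rule)
  expect_true(all(c("method", "image_id", "score") %in% names(td)))
})

test_that("autoplot and score plots return ggplot objects", {
  fx <- cv_fixture()
  res <- cv_scores(fx$features, fx$manifest, method = "rule", k = 3, seed = 2)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
  m <- image_metrics(fx$features, 0.15, 0.15)
  expect_s3_class(plot_image_metrics(m, fx$manifest), "ggplot")
})
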