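tiny_manifest <- function(n_healthy, n_patho, diagnosis = "ak") {
  tibble::tibble(
    image_id = c(sprintf("h%02d", seq_len(n_healthy)),
                 sprintf("p%02d", seq_len(n_patho))),
    diagnosis = c(rep("healthy", n_healthy), rep(diagnosis, n_patho))
  )
}

test_that("weak labels propagate the image diagnosis to every cell", {
  man <- tiny_manifest(2, 1)
  fe <- tibble::tibble(
    image_id = rep(man$image_id, times = c(10, 10, 5)),
    nucleus_id = c(1:10, 1:10, 1:5)
  )
  lab <- weak_labels(fe, man)
  expect_equal(sum(lab$weak_label == 0), 20)
  expect_equal(sum(lab$weak_label == 1), 5)
  # constant within image
  expect_true(all(tapply(lab$weak_label, lab$image_id,
                         function(x) length(unique(x))) == 1))
  man$diagnosis[1] <- "warts"
  expect_error(weak_labels(fe, man), "Unknown diagnosis")
})

test_that("stratified folds balance size and class proportions", {
  # the standard cohort layout: 114 healthy + 71 pathological, 5 folds
  man <- tibble::tibble(
    image_id = sprintf("i%03d", 1:185),
    diagnosis = c(rep("healthy", 114), rep("subclinical_ak", 34),
                  rep("ak", 30), rep("bowen", 7))
  )
  f <- stratified_folds(man, k = 5, seed = 42)
  expect_equal(as.integer(sort(table(f$fold))), rep(37L, 5))
  healthy_per_fold <- table(f$fold[man$diagnosis == "healthy"])
  expect_lte(max(healthy_per_fold) - min(healthy_per_fold), 1)

  # perfect stratification at 5 + 5 images
  man10 <- tiny_manifest(5, 5)
  f10 <- stratified_folds(man10, k = 5, seed = 1)
  tab <- table(f10$fold, is_pathological(man10$diagnosis))
  expect_true(all(tab == 1))

  # determinism contract
  expect_identical(stratified_folds(man, 5, seed = 7),
                   stratified_folds(man, 5, seed = 7))
  expect_false(identical(stratified_folds(man, 5, seed = 7)$fold,
                         stratified_folds(man, 5, seed = 8)$fold))
  expect_error(stratified_folds(tiny_manifest(10, 3), k = 5), "minority")
})

test_that("logistic training z-normalizes with training statistics", {
  set.seed(3)
  x <- matrix(rnorm(200 * 4, mean = 5, sd = 3), 200, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(200, 1, 0.5)
  fit <- fit_logistic(x, y)
  z <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, function(v) sqrt(mean((v - mean(v))^2))) - 1)),
            1e-9)
  # zero coefficients give p = 0.5 everywhere
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_equal(predict(fit0, x), rep(0.5, 200))
  expect_error(fit_logistic(x, rep(1, 200)), "single class")
})

test_that("an enlarged pathological population yields a positive volume coefficient", {
  set.seed(14)
  n <- 400
  x <- cbind(volume = c(rnorm(n / 2, 150, 30), rnorm(n / 2, 240, 30)),
             compactness = rnorm(n, 0.75, 0.05),
             neighbor_dist = rnorm(n, 25, 3))
  y <- rep(c(0, 1), each = n / 2)
  fit <- fit_logistic(x, y)
  expect_gt(fit$coefficients[["volume"]], 0)
  td <- generics::tidy(fit)
  expect_true(all(c("term", "estimate") %in% names(td)))
})

test_that("boosted trees separate separable clusters and are bit-reproducible", {
  set.seed(6)
  x <- rbind(matrix(rnorm(150 * 3, 0, 0.3), ncol = 3),
             matrix(rnorm(150 * 3, 4, 0.3), ncol = 3))
  colnames(x) <- paste0("f", 1:3)
  y <- rep(c(0, 1), each = 150)
  fit <- fit_gbt(x, y, seed = 5)
  p <- predict(fit, x)
  # the 0.3 learning rate saturates near (not at) the 0.99 mark
  expect_gte(median(p[y == 1]), 0.98)
  expect_lte(median(p[y == 0]), 0.02)
  expect_equal(auc_mw(p, y), 1)
  expect_identical(p, predict(fit_gbt(x, y, seed = 5), x))
  expect_error(fit_gbt(x, rep(0, 300), seed = 1), "single class")
})

test_that("boosted trees on pure noise stay near chance on held-out data", {
  aucs <- vapply(1:3, function(s) {
    set.seed(100 + s)
    x <- matrix(rnorm(400 * 5), 400, 5)
    y <- rep(c(0, 1), 200)
    tr <- 1:300
    fit <- fit_gbt(x[tr, ], y[tr], seed = s)
    auc_mw(predict(fit, x[-tr, ]), y[-tr])
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})
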