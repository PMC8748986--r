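test_that("simulation is bit-reproducible and honors the hard-core distance", {
  dirs <- shared_dirs()
  p <- tissue_params(hardcore_min_dist = 8)
  a <- simulate_image(p, "healthy", dirs = dirs, seed = 33)
  b <- simulate_image(p, "healthy", dirs = dirs, seed = 33)
  expect_identical(a$shapes, b$shapes)
  ctr <- as.matrix(a$shapes[c("cx_um", "cy_um", "cz_um")])
  expect_gte(min(dist(ctr)), 8)
  expect_true(all(ctr[, 1] >= 0 & ctr[, 1] <= 300))
  expect_true(all(ctr[, 3] >= 0 & ctr[, 3] <= 100))
})

test_that("requested counts follow density x area and realized density tracks the target", {
  dirs <- shared_dirs()
  # 1000 / mm^2 on 1.2 x 0.5 mm requests 600 nuclei on average
  p <- tissue_params(fov_x_mm = 1.2, fov_y_mm = 0.5, target_density = 1000,
                     image_density_jitter_gsd = 1, hardcore_min_dist = 5)
  n <- nrow(simulate_image(p, "healthy", dirs = dirs, seed = 4)$shapes)
  expect_lt(abs(n - 600), 5 * sqrt(600))
  # cohort-level realized density within 5% of the healthy preset target
  coh <- simulate_cohort(c(healthy = 25), presets = tissue_presets(),
                         seed = 77, dirs = dirs)
  dens <- nrow(coh$shapes) / 25 / (0.3 * 0.2)
  expect_lt(abs(dens / 10000 - 1), 0.05)
})

test_that("realized volumes follow the lognormal law and zero roughness gives spheres", {
  dirs <- shared_dirs()
  p <- tissue_params(image_volume_jitter_gsd = 1)
  sim <- simulate_image(p, "healthy", dirs = dirs, seed = 10)
  m <- shape_metrics(sim$shapes, dirs)
  expect_gt(nrow(m), 500)
  expect_lt(abs(median(m$volume) / 150 - 1), 0.10)
  # compactness target 1 maps to amplitude 0: discretized spheres
  psph <- tissue_params(compactness_mean = 1, compactness_sd = 0,
                        image_compactness_jitter_sd = 0,
                        image_volume_jitter_gsd = 1)
  msph <- shape_metrics(simulate_image(psph, "healthy", dirs = dirs,
                                       seed = 2)$shapes, dirs)
  expect_true(all(abs(msph$compactness - 1) < 0.02))
  expect_lt(abs(median(msph$volume) / 150 - 1), 0.10)
})

test_that("cohorts are reproducible with the documented class layout", {
  dirs <- shared_dirs()
  # the default layout totals 185 images across the four classes
  defaults <- formals(simulate_cohort)$n_per_class
  expect_equal(sum(eval(defaults)), 185)
  small <- c(healthy = 2, subclinical_ak = 1, ak = 1, bowen = 1)
  a <- simulate_cohort(small, seed = 5, dirs = dirs)
  b <- simulate_cohort(small, seed = 5, dirs = dirs)
  expect_identical(a$shapes, b$shapes)
  expect_identical(a$manifest, b$manifest)
  expect_equal(nrow(a$manifest), 5)
  expect_equal(sort(unique(a$manifest$diagnosis)),
               sort(names(small)))
  expect_error(simulate_cohort(c(healthy = 1, cyst = 1), seed = 1,
                               dirs = dirs), "preset")
})

test_that("pathological presets shift the image metrics in the pathological directions", {
  dirs <- shared_dirs()
  pres <- tissue_presets()
  mh <- lapply(1:4, function(i) {
    s <- simulate_image(pres$healthy, "healthy", dirs = dirs, seed = 400 + i)
    fe <- cell_features(s$shapes,
                        edge_geometry(build_graph(s$shapes), s$shapes, dirs),
                        dirs)
    image_metrics(dplyr::mutate(fe, image_id = paste0("h", i)), 0.3, 0.2)
  })
  mp <- lapply(1:4, function(i) {
    s <- simulate_image(pres$bowen, "bowen", dirs = dirs, seed = 500 + i)
    fe <- cell_features(s$shapes,
                        edge_geometry(build_graph(s$shapes), s$shapes, dirs),
                        dirs)
    image_metrics(dplyr::mutate(fe, image_id = paste0("p", i)), 0.3, 0.2)
  })
  h <- dplyr::bind_rows(mh); p <- dplyr::bind_rows(mp)
  expect_lt(mean(p$cell_density), mean(h$cell_density))
  expect_gt(mean(p$mean_volume), mean(h$mean_volume))
  expect_gt(mean(p$std_volume), mean(h$std_volume))
  expect_lt(mean(p$mean_compactness), mean(h$mean_compactness))
  expect_gt(mean(p$mean_neighbor_dist), mean(h$mean_neighbor_dist))
})
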