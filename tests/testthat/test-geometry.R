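test_that("sphere metrics approach the analytic values from below", {
  r <- 5
  v_true <- 4 / 3 * pi * r^3
  a_true <- 4 * pi * r^2
  prev_v <- 0
  for (n in c(96, 384)) {
    dirs <- direction_set(n)
    m <- shape_metrics(shape_table(c(3, -7, 11), matrix(r, 1, n)), dirs)
    expect_lt(m$volume, v_true)
    expect_lt(m$area, a_true)
    expect_gt(m$volume, prev_v) # refinement only adds volume
    prev_v <- m$volume
  }
  # and the deficit shrinks roughly like 1/n
  d96 <- 1 - shape_metrics(shape_table(c(0, 0, 0), matrix(r, 1, 96)),
                           direction_set(96))$volume / v_true
  d384 <- 1 - prev_v / v_true
  expect_lt(d384, d96 / 3)
})

test_that("volume and area obey the scaling laws and compactness is scale-free", {
  dirs <- shared_dirs()
  s <- random_shape_table(3, dirs, seed = 7)
  m1 <- shape_metrics(s, dirs)
  rc <- ray_cols(96)
  s2 <- s
  s2[rc] <- s[rc] * 2
  m2 <- shape_metrics(s2, dirs)
  expect_equal(m2$volume, 8 * m1$volume, tolerance = 1e-12)
  expect_equal(m2$area, 4 * m1$area, tolerance = 1e-12)
  expect_equal(m2$compactness, m1$compactness, tolerance = 1e-12)
})

test_that("compactness closed forms and isoperimetric bound hold", {
  r <- runif(1, 0.5, 20)
  expect_equal(compactness(4 / 3 * pi * r^3, 4 * pi * r^2), 1, tolerance = 1e-14)
  expect_equal(compactness(1, 6), 0.80600, tolerance = 1e-5)
  expect_equal(compactness(1 / (6 * sqrt(2)), sqrt(3)), 0.67114, tolerance = 1e-5)
  expect_error(compactness(-1, 3), "positive")
  expect_error(compactness(1, 0), "positive")
  # every generated shape respects compactness <= 1
  dirs <- shared_dirs()
  m <- shape_metrics(random_shape_table(25, dirs, seed = 3, rough = 0.35), dirs)
  expect_true(all(m$compactness <= 1 + 1e-9))
  expect_true(all(m$area >= (36 * pi * m$volume^2)^(1 / 3) - 1e-9))
})

test_that("mesh volume matches the convex-hull oracle for cospherical endpoints", {
  dirs <- shared_dirs()
  for (r in c(1, 4.7, 12)) {
    m <- shape_metrics(shape_table(c(0, 0, 0), matrix(r, 1, 96)), dirs)
    hv <- convex_hull_volume(dirs$directions * r)
    expect_equal(m$volume, hv, tolerance = 1e-9)
  }
})

test_that("cube-sampled shape recovers the cube volume up to discretization", {
  dirs <- shared_dirs()
  rays <- cube_rays(dirs, 10)
  m <- shape_metrics(shape_table(c(0, 0, 0), matrix(rays, 1)), dirs)
  hv <- convex_hull_volume(dirs$directions * rays)
  # corners are sampled only approximately at 96 rays, so both sit below
  # the true cube volume by the discretization deficit
  expect_equal(m$volume, 1000, tolerance = 0.10)
  expect_equal(hv, 1000, tolerance = 0.10)
  expect_lte(m$volume, hv + 1e-6) # the radial mesh cannot exceed the hull
  expect_lte(hv, 1000 + 1e-6)
})

test_that("radial extent is exact at nodes, constant fields, and matches the brute oracle", {
  dirs <- shared_dirs()
  set.seed(42)
  rays <- 4 * (1 + runif(96, -0.3, 0.3))
  # node exactness
  for (i in c(1, 37, 96)) {
    expect_equal(radial_extent(rays, dirs, dirs$directions[i, ]), rays[i],
                 tolerance = 1e-12)
  }
  # constant field
  u <- matrix(rnorm(30), 10, 3)
  expect_equal(radial_extent(sphere_rays(dirs, 6.5), dirs, u),
               rep(6.5, 10), tolerance = 1e-12)
  # brute-force face-search oracle on random directions
  for (k in 1:20) {
    uu <- rnorm(3); uu <- uu / sqrt(sum(uu^2))
    expect_equal(radial_extent(rays, dirs, uu),
                 brute_radial_extent(rays, dirs, uu), tolerance = 1e-6)
  }
  expect_error(radial_extent(rays, dirs, c(0, 0, 0)), "nonzero")
})

test_that("voxel masks convert to shapes with correct geometry", {
  dirs <- direction_set(64)
  # digitized ball, radius 10 um at 1 um isotropic spacing
  n <- 25
  ax <- (seq_len(n) - 0.5) - 12.5
  ball <- array(0, c(n, n, n))
  for (z in seq_len(n)) ball[z, , ] <- outer(ax, ax, function(y, x)
    as.numeric(ax[z]^2 + y^2 + x^2 <= 100))
  sh <- voxels_to_shape(ball, c(1, 1, 1), dirs)
  rays <- as.numeric(sh[ray_cols(64)])
  expect_true(all(abs(rays - 10) <= 1))
  # single voxel floors at half a voxel diagonal
  single <- array(0, c(3, 3, 3)); single[2, 2, 2] <- 1
  s1 <- voxels_to_shape(single, c(1, 1, 1), dirs)
  expect_equal(as.numeric(s1[ray_cols(64)]),
               rep(sqrt(3) / 2, 64), tolerance = 1e-9)
  # empty mask errors
  expect_error(voxels_to_shape(array(0, c(2, 2, 2)), c(1, 1, 1), dirs),
               "empty instance")
})

test_that("digitized ellipsoid round-trips to its analytic volume within 5%", {
  # 384 rays: the mesh discretization deficit (~6% at 96 rays) drops
  # below the 5% round-trip budget
  dirs <- direction_set(384)
  nz <- 16; ny <- 20; nx <- 28
  az <- (seq_len(nz) - 0.5) * 1 - 8  # 1 um spacing in z
  ay <- (seq_len(ny) - 0.5) * 1 - 10
  axx <- (seq_len(nx) - 0.5) * 1 - 14
  vol <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) vol[z, , ] <- outer(ay, axx, function(y, x)
    as.numeric((x / 12)^2 + (y / 8)^2 + (az[z] / 6)^2 <= 1))
  sh <- voxels_to_shape(vol, c(1, 1, 1), dirs)
  v_mesh <- shape_metrics(sh, dirs)$volume
  v_true <- 4 / 3 * pi * 12 * 8 * 6
  v_voxel <- sum(vol) # voxel-count oracle, 1 um^3 voxels
  expect_equal(v_mesh / v_true, 1, tolerance = 0.05)
  expect_equal(v_voxel / v_true, 1, tolerance = 0.05)
})
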