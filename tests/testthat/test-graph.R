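regular_tetra <- function(edge) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  v * edge / sqrt(8)
}

test_that("small complete-graph cases follow the cutoff", {
  dirs <- direction_set(16)
  ctr <- regular_tetra(30)
  s <- shape_table(ctr, matrix(2, 4, 16))
  g <- build_graph(s, cutoff = 50)
  expect_equal(nrow(g$edges), 6)
  expect_true(all(g$nodes$degree == 3))
  expect_equal(g$edges$d_center_um, rep(30, 6), tolerance = 1e-9)

  g60 <- build_graph(shape_table(regular_tetra(60), matrix(2, 4, 16)),
                     cutoff = 50)
  expect_equal(nrow(g60$edges), 0)
  expect_true(all(g60$nodes$degree == 0))
})

test_that("Delaunay edges match the brute-force empty-circumsphere oracle", {
  dirs <- direction_set(8)
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    n <- 20
    ctr <- matrix(runif(3 * n, 0, 100), n, 3)
    s <- shape_table(ctr, matrix(1, n, 8))
    g <- build_graph(s, cutoff = Inf)
    expect_identical(edge_keys(g), brute_delaunay_edges(ctr))
  }
})

test_that("raising the cutoff only adds edges, up to the full Delaunay set", {
  dirs <- direction_set(8)
  set.seed(11)
  s <- shape_table(matrix(runif(150, 0, 80), 50, 3), matrix(1, 50, 8))
  prev <- character(0)
  for (cut in c(10, 25, 40, 80, Inf)) {
    ek <- edge_keys(build_graph(s, cutoff = cut))
    expect_true(all(prev %in% ek))
    prev <- ek
  }
  expect_identical(prev, edge_keys(build_graph(s, cutoff = Inf)))
})

test_that("graph is invariant under node relabeling", {
  set.seed(4)
  ctr <- matrix(runif(60, 0, 60), 20, 3)
  s <- shape_table(ctr, matrix(1, 20, 8), nucleus_id = 1:20)
  perm <- sample(20)
  s2 <- s[perm, ]
  expect_identical(edge_keys(build_graph(s, cutoff = 40)),
                   edge_keys(build_graph(s2, cutoff = 40)))
})

test_that("interior Poisson-Delaunay mean degree matches 48*pi^2/35 + 2", {
  set.seed(2024)
  n <- 5000
  box <- 500
  ctr <- matrix(runif(3 * n, 0, box), n, 3)
  s <- shape_table(ctr, matrix(1, n, 8))
  g <- build_graph(s, cutoff = Inf)
  deg <- g$nodes$degree
  # restrict to nodes away from the boundary (expected spacing ~ 10.8)
  margin <- 75
  interior <- apply(ctr > margin & ctr < box - margin, 1, all)
  mu <- mean(deg[interior])
  se <- sd(deg[interior]) / sqrt(sum(interior))
  expect_lt(abs(mu - (48 * pi^2 / 35 + 2)), 3 * se)
})

test_that("border distances follow the collinear-sphere geometry and clamp at overlap", {
  dirs <- shared_dirs()
  two <- function(d) {
    shape_table(rbind(c(0, 0, 0), c(d, 0, 0)),
                rbind(sphere_rays(dirs, 6), sphere_rays(dirs, 4)))
  }
  g <- edge_geometry(build_graph(two(20)), two(20), dirs)
  expect_equal(g$edges$d_center_um, 20)
  expect_equal(g$edges$d_border_um, 10, tolerance = 1e-9)

  g9 <- edge_geometry(build_graph(two(9)), two(9), dirs)
  expect_equal(g9$edges$d_border_um, 0)

  # random shapes: d_border agrees with the brute radial-field oracle
  s <- random_shape_table(6, dirs, seed = 5, box = 40)
  g <- edge_geometry(build_graph(s, cutoff = Inf), s, dirs)
  ctr <- as.matrix(s[c("cx_um", "cy_um", "cz_um")])
  rmat <- as.matrix(s[ray_cols(96)])
  for (e in seq_len(nrow(g$edges))) {
    i <- g$edges$id_a[e]; j <- g$edges$id_b[e]
    u <- ctr[j, ] - ctr[i, ]; d <- sqrt(sum(u^2)); u <- u / d
    ora <- max(0, d - brute_radial_extent(rmat[i, ], dirs, u) -
                 brute_radial_extent(rmat[j, ], dirs, -u))
    expect_equal(g$edges$d_border_um[e], ora, tolerance = 1e-6)
    expect_lte(g$edges$d_border_um[e], g$edges$d_center_um[e])
  }
})

test_that("coincident centers yield zero distances with a warning", {
  dirs <- direction_set(16)
  s <- shape_table(rbind(c(0, 0, 0), c(0, 0, 0), c(10, 0, 0)),
                   matrix(3, 3, 16))
  g <- build_graph(s, cutoff = 50)
  expect_warning(g <- edge_geometry(g, s, dirs), "coincident")
  z <- g$edges[g$edges$d_center_um == 0, ]
  expect_true(all(z$d_border_um == 0))
})

test_that("degenerate coplanar configurations fall back gracefully", {
  dirs <- direction_set(8)
  # 6 coplanar points: jitter (1e-4) resolves the triangulation
  ctr <- cbind(runif(6, 0, 30), runif(6, 0, 30), 5)
  s <- shape_table(ctr, matrix(1, 6, 8))
  g <- build_graph(s, cutoff = Inf)
  expect_gt(nrow(g$edges), 0)
  expect_error(build_graph(shape_table(matrix(c(1, 2, NaN), 1, 3),
                                       matrix(1, 1, 8))),
               "non-finite")
})
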