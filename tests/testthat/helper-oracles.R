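# Independent oracles, deliberately written as plain brute force: they
# recompute what the package computes through different code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Delaunay edges by empty-circumsphere enumeration over all 4-point
# subsets (general-position inputs only; O(n^5), keep n small).
brute_delaunay_edges <- function(pts) {
  n <- nrow(pts)
  combs <- utils::combn(n, 4)
  keys <- character(0)
  for (ci in seq_len(ncol(combs))) {
    id <- combs[, ci]
    A <- pts[id, , drop = FALSE]
    M <- 2 * sweep(A[2:4, , drop = FALSE], 2, A[1, ])
    rhs <- rowSums(A[2:4, , drop = FALSE]^2) - sum(A[1, ]^2)
    cc <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(cc)) next
    r2 <- sum((A[1, ] - cc)^2)
    d2 <- rowSums(sweep(pts, 2, cc)^2)
    if (all(d2[-id] > r2 * (1 + 1e-9))) {
      pr <- utils::combn(id, 2)
      keys <- c(keys, apply(pr, 2, function(e) paste(sort(e), collapse = "-")))
    }
  }
  sort(unique(keys))
}

edge_keys <- function(graph) {
  if (nrow(graph$edges) == 0) return(character(0))
  sort(apply(cbind(graph$edges$id_a, graph$edges$id_b), 1,
             function(e) paste(sort(e), collapse = "-")))
}

# canonical ray fields
sphere_rays <- function(dirs, r) rep(r, dirs$n_rays)
cube_rays <- function(dirs, side) {
  (side / 2) / apply(abs(dirs$directions), 1, max)
}
ellipsoid_rays <- function(dirs, abc) {
  1 / sqrt(colSums((t(dirs$directions) / abc)^2))
}

# boundary distance along u by exhaustive face search + Cramer solve
# (tolerance-based containment, unlike the package's argmax search)
brute_radial_extent <- function(rays, dirs, u) {
  u <- u / sqrt(sum(u^2))
  for (f in seq_len(nrow(dirs$faces))) {
    D <- t(dirs$directions[dirs$faces[f, ], , drop = FALSE]) # columns d1,d2,d3
    det3 <- function(M) {
      M[1, 1] * (M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2]) -
        M[1, 2] * (M[2, 1] * M[3, 3] - M[2, 3] * M[3, 1]) +
        M[1, 3] * (M[2, 1] * M[3, 2] - M[2, 2] * M[3, 1])
    }
    dd <- det3(D)
    a <- numeric(3)
    for (j in 1:3) {
      Dj <- D; Dj[, j] <- u
      a[j] <- det3(Dj) / dd
    }
    if (all(a >= -1e-10)) {
      w <- pmax(a, 0); w <- w / sum(w)
      return(sum(w * rays[dirs$faces[f, ]]))
    }
  }
  stop("no containing face found")
}

# naive per-cell recomputation of the 13 features from an edge list
brute_cell_features <- function(sm, edges) {
  ids <- sm$nucleus_id
  out <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    inc <- which(edges$id_a == id | edges$id_b == id)
    vol <- sm$volume[i]; comp <- sm$compactness[i]
    row <- list(nucleus_id = id, volume = vol, compactness = comp,
                volume_over_compactness = vol / comp,
                nb_neighbours = length(inc))
    if (length(inc) == 0) {
      row <- c(row, list(neighbor_dist = NA_real_, border_dist = NA_real_,
                         border_over_neigh_distances = NA_real_,
                         neighbours_avg_volumes = NA_real_,
                         neighbours_avg_compactness = NA_real_,
                         neighbours_std_volumes = NA_real_,
                         neighbours_std_compactness = NA_real_,
                         volume_neigh_ratio = NA_real_,
                         compactness_neigh_ratio = NA_real_))
    } else {
      nb <- ifelse(edges$id_a[inc] == id, edges$id_b[inc], edges$id_a[inc])
      j <- match(nb, ids)
      psd <- function(x) sqrt(sum((x - mean(x))^2) / length(x))
      row <- c(row, list(
        neighbor_dist = mean(edges$d_center_um[inc]),
        border_dist = mean(edges$d_border_um[inc]),
        border_over_neigh_distances =
          mean(edges$d_border_um[inc] / edges$d_center_um[inc]),
        neighbours_avg_volumes = mean(sm$volume[j]),
        neighbours_avg_compactness = mean(sm$compactness[j]),
        neighbours_std_volumes = psd(sm$volume[j]),
        neighbours_std_compactness = psd(sm$compactness[j]),
        volume_neigh_ratio = vol / mean(sm$volume[j]),
        compactness_neigh_ratio = comp / mean(sm$compactness[j])))
    }
    out[[i]] <- tibble::as_tibble(row)
  }
  dplyr::bind_rows(out)
}

# all-pairs AUC, ties counted one half
pair_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# pooled-variance two-sample t closed form (group1 minus group2)
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, p = 2 * pt(-abs(tt), na + nb - 2))
}

pearson_oracle <- function(a, b) {
  n <- length(a)
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), n - 2))
}

# shared fixtures: a direction set is expensive enough to build once
shared_dirs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- direction_set(96)
    cache
  }
})

random_shape_table <- function(n, dirs, seed, box = 120, rmin = 2.5,
                               rmax = 5.5, rough = 0.15) {
  set.seed(seed)
  ctr <- matrix(runif(3 * n, 0, box), n, 3)
  rays <- matrix(NA_real_, n, dirs$n_rays)
  for (i in seq_len(n)) {
    r <- runif(1, rmin, rmax)
    rays[i, ] <- r * (1 + runif(dirs$n_rays, -rough, rough))
  }
  shape_table(ctr, rays)
}
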