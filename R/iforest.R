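# Isolation forest, from scratch (no labels consumed). Follows the
# original algorithm with the hyperparameters commonly shipped as library
# defaults: 100 trees, subsample size psi = min(256, n), depth cap
# ceiling(log2(psi)), anomaly score s(x) = 2^(-E[h(x)] / c(psi)) where
# h(x) is the path length augmented by c(size) at external nodes and
# c(m) = 2 H(m-1) - 2 (m-1)/m is the average BST path length.

avg_path_length <- function(m) {
  out <- numeric(length(m))
  out[m == 2] <- 1
  big <- m > 2
  if (any(big)) {
    mm <- m[big]
    out[big] <- 2 * (log(mm - 1) + 0.5772156649015329) - 2 * (mm - 1) / mm
  }
  out
}

grow_itree <- function(x, rows, depth_cap) {
  feature <- integer(0); split <- numeric(0)
  left <- integer(0); right <- integer(0)
  depth <- integer(0); size <- integer(0)
  new_node <- function() {
    k <- length(feature) + 1L
    feature[k] <<- 0L; split[k] <<- NA_real_
    left[k] <<- 0L; right[k] <<- 0L; depth[k] <<- 0L; size[k] <<- 0L
    k
  }
  build <- function(rows, d) {
    k <- new_node()
    depth[k] <<- d; size[k] <<- length(rows)
    if (length(rows) <= 1L || d >= depth_cap) return(k)
    sub <- x[rows, , drop = FALSE]
    rng <- apply(sub, 2, range)
    varying <- which(rng[2, ] > rng[1, ])
    if (length(varying) == 0) return(k)
    j <- if (length(varying) == 1) varying else sample(varying, 1)
    sp <- runif(1, rng[1, j], rng[2, j])
    go_left <- sub[, j] < sp
    if (!any(go_left) || all(go_left)) return(k)
    feature[k] <<- j; split[k] <<- sp
    left[k] <<- build(rows[go_left], d + 1L)
    right[k] <<- build(rows[!go_left], d + 1L)
    k
  }
  root <- build(rows, 0L)
  list(feature = feature, split = split, left = left, right = right,
       depth = depth, size = size, root = root)
}

#' Fit an isolation forest anomaly scorer
#'
#' Unsupervised: cells that are easy to isolate by random axis-aligned
#' splits (few splits to single them out) receive high anomaly scores.
#' No labels are consumed.
#'
#' @param x Numeric matrix or data frame of features (rows = cells).
#' @param n_trees Number of isolation trees (default 100).
#' @param max_samples Subsample size per tree (default 256, capped at n).
#' @param seed Seed for subsampling and split randomness.
#' @return An object of class `isolation_forest`.
#' @export
fit_isolation_forest <- function(x, n_trees = 100, max_samples = 256,
                                 seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stop("isolation forest needs at least 2 cells")
  if (anyNA(x)) stop("isolation forest input must have no missing values")
  psi <- min(max_samples, n)
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(t) {
      rows <- sample.int(n, psi)
      grow_itree(x, rows, ceiling(log2(psi)))
    })
  })
  structure(
    list(trees = trees, psi = psi, n_trees = n_trees,
         c_psi = avg_path_length(psi), seed = seed,
         n_features = ncol(x), feature_names = colnames(x)),
    class = "isolation_forest"
  )
}

#' @export
print.isolation_forest <- function(x, ...) {
  cat("<isolation_forest> ", x$n_trees, " trees, subsample ", x$psi, "\n",
      sep = "")
  invisible(x)
}

#' Anomaly scores from an isolation forest
#'
#' @param object A fitted [fit_isolation_forest()] model.
#' @param newdata Feature matrix/data frame with the training columns.
#' @param ... Unused.
#' @return Numeric vector of raw anomaly scores in (0, 1); higher = more
#'   anomalous (shorter average isolation path).
#' @export
predict.isolation_forest <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$n_features) stop("feature count mismatch")
  m <- nrow(x)
  total <- numeric(m)
  for (tr in object$trees) {
    node <- rep.int(tr$root, m)
    repeat {
      internal <- tr$feature[node] > 0L
      if (!any(internal)) break
      idx <- which(internal)
      nd <- node[idx]
      goes_left <- x[cbind(idx, tr$feature[nd])] < tr$split[nd]
      node[idx] <- ifelse(goes_left, tr$left[nd], tr$right[nd])
    }
    extra <- ifelse(tr$size[node] > 1, avg_path_length(tr$size[node]), 0)
    total <- total + tr$depth[node] + extra
  }
  2^(-(total / object$n_trees) / object$c_psi)
}
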