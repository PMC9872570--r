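#' Clustering result container
#'
#' All clustering functions return a `clustering` object: integer labels
#' per row (`-1` reserved for DBSCAN noise), the number of non-noise
#' clusters `k`, and — where centroids are defined — the inertia, reported
#' as the MEAN squared distance from each point to its assigned centroid.
#' The more common sum-based inertia is this value times `n`; both give
#' identical cluster assignments and elbow choices, the mean is simply the
#' scale used throughout this package.
#'
#' @param labels Integer vector of cluster labels.
#' @param inertia Mean squared distance to assigned centroid, or `NA`.
#' @param centers Optional centroid matrix.
#' @param method Character tag.
#' @return An object of class `clustering`.
#' @export
clustering <- function(labels, inertia = NA_real_, centers = NULL,
                       method = "unknown") {
  k <- length(unique(labels[labels != -1L]))
  structure(list(labels = as.integer(labels), k = k, inertia = inertia,
                 centers = centers, method = method),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  noise <- sum(x$labels == -1L)
  cat(sprintf("<clustering> method=%s k=%d n=%d%s%s\n", x$method, x$k,
              length(x$labels),
              if (!is.na(x$inertia)) sprintf(" inertia=%.4g", x$inertia) else "",
              if (noise) sprintf(" noise=%d", noise) else ""))
  invisible(x)
}

# mean squared distance of points to their assigned centers
mean_inertia <- function(X, labels, centers) {
  d2 <- rowSums((X - centers[labels, , drop = FALSE])^2)
  mean(d2)
}

#' K-means++ clustering
#'
#' Lloyd's algorithm with k-means++ seeding: the first center is chosen
#' uniformly at random from the data, each subsequent center with
#' probability proportional to the squared distance to the nearest center
#' already chosen. Iterations stop when the maximum centroid shift drops
#' below `tol` or after `max_iter` sweeps; the best of `n_init` restarts
#' by inertia is returned. If a cluster empties during Lloyd iteration,
#' the point farthest from its centroid is reassigned to it (logged).
#'
#' @param X Numeric matrix, one row per observation.
#' @param k Number of clusters (`<= nrow(X)`).
#' @param n_init Number of random restarts (default 10).
#' @param max_iter Maximum Lloyd sweeps per restart (default 100).
#' @param tol Convergence threshold on centroid movement (default 1e-6).
#' @param seed Optional integer seed.
#' @return A [clustering()] with labels `1..k`, centers and mean inertia.
#' @export
kmeanspp <- function(X, k, n_init = 10L, max_iter = 100L, tol = 1e-6,
                     seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(k >= 1L, k <= n)
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (rep in seq_len(n_init)) {
    centers <- kmeanspp_seed(X, k)
    labels <- integer(n)
    for (it in seq_len(max_iter)) {
      d2 <- point_center_dist2(X, centers)
      labels <- max.col(-d2, ties.method = "first")
      new_centers <- centers
      for (j in seq_len(k)) {
        members <- which(labels == j)
        if (!length(members)) {
          # empty cluster: seize the point farthest from its current centroid
          far <- which.max(d2[cbind(seq_len(n), labels)])
          vlog("empty cluster %d: reassigning farthest point %d", j, far)
          labels[far] <- j
          members <- far
        }
        new_centers[j, ] <- colMeans(X[members, , drop = FALSE])
      }
      shift <- max(sqrt(rowSums((new_centers - centers)^2)))
      centers <- new_centers
      if (shift < tol) break
    }
    d2 <- point_center_dist2(X, centers)
    labels <- max.col(-d2, ties.method = "first")
    inertia <- mean(d2[cbind(seq_len(n), labels)])
    if (is.null(best) || inertia < best$inertia) {
      best <- list(labels = labels, centers = centers, inertia = inertia)
    }
  }
  clustering(best$labels, best$inertia, best$centers, method = "kmeans++")
}

kmeanspp_seed <- function(X, k) {
  n <- nrow(X)
  centers <- X[sample.int(n, 1L), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(point_center_dist2(X, centers), 1, min)
    idx <- if (sum(d2) == 0) sample.int(n, 1L) else
      sample.int(n, 1L, prob = d2 / sum(d2))
    centers <- rbind(centers, X[idx, , drop = FALSE])
  }
  centers
}

# squared Euclidean distances, points x centers
point_center_dist2 <- function(X, centers) {
  cross <- X %*% t(centers)
  d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) - 2 * cross +
    outer(rep(1, nrow(X)), rowSums(centers^2))
  pmax(d2, 0)
}

#' DBSCAN density clustering
#'
#' Standard density-reachability expansion: points with at least
#' `min_samples` neighbors within `eps` (self included) are core points;
#' clusters are the connected components of core points under the eps
#' relation, plus any border points within `eps` of a core. Points
#' reachable from no core are labeled noise (`-1`). Core and border
#' assignment is deterministic given the input row order.
#'
#' @param X Numeric matrix, one row per observation.
#' @param eps Neighborhood radius (`> 0`).
#' @param min_samples Core-point threshold (`>= 1`).
#' @return A [clustering()]; inertia is `NA` (no centroids).
#' @export
dbscan_cluster <- function(X, eps, min_samples) {
  X <- as.matrix(X)
  stopifnot(eps > 0, min_samples >= 1L)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  neighbors <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(neighbors, length, integer(1)) >= min_samples
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- neighbors[[i]]
    while (length(queue)) {
      j <- queue[1L]
      queue <- queue[-1L]
      if (labels[j] == -1L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, neighbors[[j]][labels[neighbors[[j]]] == -1L])
      }
    }
  }
  clustering(labels, method = "dbscan")
}

#' Spectral clustering
#'
#' Low-dimensional embedding of the RBF affinity matrix
#' `W[i,j] = exp(-gamma * ||x_i - x_j||^2)` followed by k-means++: the
#' symmetric normalized affinity `D^{-1/2} W D^{-1/2}` is eigendecomposed,
#' the rows of the `k` leading eigenvectors are normalized to unit length,
#' and the embedded rows are clustered with [kmeanspp()].
#'
#' @inheritParams kmeanspp
#' @param gamma RBF affinity width (default 1, on standardized features).
#' @return A [clustering()] with labels `1..k`.
#' @export
spectral_cluster <- function(X, k, gamma = 1.0, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(k >= 1L, k <= n)
  if (k == 1L) return(clustering(rep(1L, n), method = "spectral"))
  W <- exp(-gamma * as.matrix(stats::dist(X))^2)
  d <- rowSums(W)
  if (any(d <= 0)) stop("degenerate affinity matrix: zero-degree row")
  Dm <- 1 / sqrt(d)
  M <- W * outer(Dm, Dm)
  eig <- tryCatch(eigen(M, symmetric = TRUE),
                  error = function(e) {
                    stop("eigendecomposition failed (condition estimate ",
                         format(kappa(M)), "): ", conditionMessage(e))
                  })
  U <- eig$vectors[, seq_len(k), drop = FALSE]
  norms <- sqrt(rowSums(U^2))
  norms[norms == 0] <- 1
  U <- U / norms
  km <- kmeanspp(U, k, seed = seed)
  clustering(km$labels, method = "spectral")
}

#' Elbow selection of the cluster count
#'
#' Runs [kmeanspp()] for each `k` in `k_range`, records the inertia curve,
#' and selects the `k` maximizing the discrete second difference
#' `inertia(k-1) - 2 inertia(k) + inertia(k+1)` — the sharpest bend of the
#' curve toward the horizontal. Endpoints of the range cannot be selected
#' (the second difference is undefined there). When no pronounced elbow
#' exists (all second differences are non-positive or the curve is
#' essentially linear) a warning is issued and the selection returned
#' anyway.
#'
#' @inheritParams kmeanspp
#' @param k_range Ascending integer vector of candidate `k`, length >= 3.
#' @return List with `k` (selected), `k_range`, `inertia` (curve) and
#'   `second_diff`.
#' @export
elbow_select <- function(X, k_range = 1:8, seed = NULL, n_init = 10L) {
  stopifnot(length(k_range) >= 3L, !is.unsorted(k_range, strictly = TRUE))
  if (!is.null(seed)) set.seed(seed)
  inertia <- vapply(k_range, function(k) kmeanspp(X, k, n_init = n_init)$inertia,
                    numeric(1))
  c(select_elbow_k(k_range, inertia), list(k_range = k_range, inertia = inertia))
}

#' @param inertia Numeric inertia curve aligned with `k_range`.
#' @rdname elbow_select
#' @export
select_elbow_k <- function(k_range, inertia) {
  stopifnot(length(k_range) == length(inertia), length(k_range) >= 3L)
  inner <- seq(2L, length(k_range) - 1L)
  d2 <- inertia[inner - 1L] - 2 * inertia[inner] + inertia[inner + 1L]
  if (max(d2) <= max(1e-12, 1e-9 * abs(inertia[1]))) {
    warning("no pronounced elbow in the inertia curve; selection is weak")
  }
  list(k = k_range[inner[which.max(d2)]], second_diff = d2)
}
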