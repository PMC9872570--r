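#' Internal clustering validity indices
#'
#' Three label-free measures of clustering quality over a numeric feature
#' matrix. Davies-Bouldin: lower is better; Calinski-Harabasz and the
#' mean silhouette: higher is better. All use Euclidean distance. Noise
#' labels (`-1`, from DBSCAN) are not accepted here — filter to non-noise
#' points first (see [cluster_metrics()], which does this and reports the
#' noise fraction alongside).
#'
#' @param X Numeric matrix, one row per observation.
#' @param labels Integer cluster labels (no `-1`).
#' @return A single numeric score.
#' @name validity-indices
NULL

check_labels <- function(X, labels, min_k = 2L) {
  stopifnot(nrow(X) == length(labels))
  if (any(labels == -1L)) {
    stop("noise labels (-1) are not allowed; filter noise points first")
  }
  k <- length(unique(labels))
  if (k < min_k) stop("need at least ", min_k, " clusters, got ", k)
  k
}

#' @describeIn validity-indices Davies-Bouldin index:
#'   `(1/k) * sum_i max_{j != i} (S_i + S_j) / M_ij`, with `S_i` the mean
#'   distance of cluster `i`'s points to its centroid and `M_ij` the
#'   distance between centroids. Two clusters sharing a centroid make the
#'   pair undefined and raise an error.
#' @export
davies_bouldin <- function(X, labels) {
  X <- as.matrix(X)
  check_labels(X, labels)
  levs <- sort(unique(labels))
  cent <- do.call(rbind, lapply(levs, function(l)
    colMeans(X[labels == l, , drop = FALSE])))
  S <- vapply(seq_along(levs), function(i) {
    pts <- X[labels == levs[i], , drop = FALSE]
    mean(sqrt(rowSums((pts - matrix(cent[i, ], nrow(pts), ncol(X),
                                    byrow = TRUE))^2)))
  }, numeric(1))
  k <- length(levs)
  r <- numeric(k)
  for (i in seq_len(k)) {
    ratios <- vapply(setdiff(seq_len(k), i), function(j) {
      M <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (M == 0) {
        stop("undefined Davies-Bouldin pair: clusters ", levs[i], " and ",
             levs[j], " have identical centroids")
      }
      (S[i] + S[j]) / M
    }, numeric(1))
    r[i] <- max(ratios)
  }
  mean(r)
}

#' @describeIn validity-indices Calinski-Harabasz index:
#'   `[BSS/(k-1)] / [WSS/(n-k)]` with between- and within-group sums of
#'   squared distances about the centroids. Zero within-group scatter
#'   returns `Inf` with a warning.
#' @export
calinski_harabasz <- function(X, labels) {
  X <- as.matrix(X)
  k <- check_labels(X, labels)
  n <- nrow(X)
  if (k >= n) stop("calinski_harabasz requires k < n")
  grand <- colMeans(X)
  levs <- sort(unique(labels))
  bss <- 0; wss <- 0
  for (l in levs) {
    pts <- X[labels == l, , drop = FALSE]
    cent <- colMeans(pts)
    bss <- bss + nrow(pts) * sum((cent - grand)^2)
    wss <- wss + sum(sweep(pts, 2, cent)^2)
  }
  if (wss == 0) {
    warning("zero within-group scatter: Calinski-Harabasz is infinite")
    return(Inf)
  }
  (bss / (k - 1)) / (wss / (n - k))
}

#' @describeIn validity-indices Mean silhouette coefficient: per point
#'   `s = (b - a) / max(a, b)`, with `a` the mean distance to the other
#'   points of its own cluster (singletons score 0) and `b` the lowest
#'   mean distance to the points of another cluster; averaged over all
#'   points. Lies in `[-1, 1]`.
#' @export
silhouette_score <- function(X, labels) {
  X <- as.matrix(X)
  check_labels(X, labels)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  levs <- sort(unique(labels))
  s <- vapply(seq_len(n), function(i) {
    own <- labels[i]
    mates <- which(labels == own)
    if (length(mates) == 1L) return(0)
    a <- mean(D[i, setdiff(mates, i)])
    b <- min(vapply(setdiff(levs, own), function(l) {
      mean(D[i, labels == l])
    }, numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Validity metrics for a clustering, with DBSCAN noise handling
#'
#' Computes the three indices of [validity-indices] over the non-noise
#' points of a [clustering()] and reports the noise fraction alongside,
#' since the indices themselves are undefined for noise labels.
#'
#' @param X Numeric feature matrix.
#' @param cl A `clustering` object (or integer label vector).
#' @return Named list: `davies_bouldin`, `calinski_harabasz`,
#'   `silhouette`, `noise_fraction`, `k`.
#' @export
cluster_metrics <- function(X, cl) {
  labels <- if (inherits(cl, "clustering")) cl$labels else as.integer(cl)
  X <- as.matrix(X)
  keep <- labels != -1L
  noise_fraction <- 1 - mean(keep)
  Xk <- X[keep, , drop = FALSE]
  lk <- labels[keep]
  k <- length(unique(lk))
  if (k < 2L || nrow(Xk) <= k) {
    return(list(davies_bouldin = NA_real_, calinski_harabasz = NA_real_,
                silhouette = NA_real_, noise_fraction = noise_fraction, k = k))
  }
  list(
    davies_bouldin = davies_bouldin(Xk, lk),
    calinski_harabasz = calinski_harabasz(Xk, lk),
    silhouette = silhouette_score(Xk, lk),
    noise_fraction = noise_fraction,
    k = k
  )
}
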