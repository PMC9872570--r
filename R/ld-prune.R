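#' Windowed linkage-disequilibrium pruning
#'
#' Removes variants whose genotype dosage vectors are highly correlated
#' with an earlier variant, so the retained panel is largely independent.
#' The classic sliding-window procedure is used: within each window of
#' `window` consecutive variants (window starts advance by `step`), every
#' pair of still-retained variants is tested and the *later* variant (in
#' position order) is dropped when the squared Pearson correlation of the
#' dosage vectors reaches `r2_threshold`. Keeping the earlier variant makes
#' the result deterministic.
#'
#' A zero-variance dosage vector (monomorphic in the cohort) has undefined
#' correlation; its r-squared is defined as 0 against any partner and the
#' case is logged, so monomorphic variants are never pruned for LD.
#'
#' @param genotypes Numeric matrix, variants in rows (ordered by
#'   chromosome and position) and patients in columns, dosage-coded
#'   0/1/2 (`NA` tolerated and dropped pairwise).
#' @param r2_threshold Squared-correlation threshold in `[0, 1]`; pairs at
#'   or above it conflict. Default 0.5.
#' @param window Window size in variants (default 50).
#' @param step Window start increment in variants (default 5).
#' @return Integer vector of retained row indices, in order.
#' @export
ld_prune <- function(genotypes, r2_threshold = 0.5, window = 50L, step = 5L) {
  stopifnot(is.matrix(genotypes), r2_threshold >= 0, r2_threshold <= 1,
            window >= 2L, step >= 1L)
  n <- nrow(genotypes)
  if (n < 2L) return(seq_len(n))
  keep <- rep(TRUE, n)
  starts <- if (n <= window) 1L else unique(c(seq(1L, n - window + 1L, by = step),
                                              n - window + 1L))
  for (s in starts) {
    idx <- s:min(s + window - 1L, n)
    for (jj in seq_along(idx)[-1L]) {
      j <- idx[jj]
      if (!keep[j]) next
      for (i in idx[seq_len(jj - 1L)]) {
        if (!keep[i]) next
        if (dosage_r2(genotypes[i, ], genotypes[j, ]) >= r2_threshold) {
          keep[j] <- FALSE
          break
        }
      }
    }
  }
  which(keep)
}

# squared Pearson correlation of two dosage vectors; 0 when either has
# zero variance over the jointly observed entries
dosage_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || stats::var(x) == 0 || stats::var(y) == 0) {
    vlog("zero-variance dosage vector: r^2 defined as 0")
    return(0)
  }
  stats::cor(x, y)^2
}
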