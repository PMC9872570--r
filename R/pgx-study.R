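#' One-sided proportion z-test for a survival rate
#'
#' Tests whether an observed survival proportion exceeds the null rate
#' `p0` with the one-sample z statistic
#' `z = (phat - p0) / sqrt(p0 (1 - p0) / n)` and upper-tail standard
#' normal p-value. No continuity correction is applied. When the normal
#' approximation is doubtful (`n p0 < 5` or `n (1 - p0) < 5`) a warning
#' is issued but the result is still returned.
#'
#' @param survivors Number of survivors (`0 <= survivors <= n`).
#' @param n Group size (`>= 1`).
#' @param p0 Null survival proportion in `(0, 1)`; default 0.5, the
#'   untreated baseline.
#' @param alternative Only `"greater"` (improvement over `p0`) is
#'   implemented.
#' @return List with `z`, `p`, `estimate` (`survivors/n`), `n`, `p0`.
#' @examples
#' ztest_survival(90, 100)  # z = 8, p ~ 6.2e-16
#' @export
ztest_survival <- function(survivors, n, p0 = 0.5, alternative = "greater") {
  stopifnot(n >= 1, survivors >= 0, survivors <= n, p0 > 0, p0 < 1)
  alternative <- match.arg(alternative, "greater")
  if (n * p0 < 5 || n * (1 - p0) < 5) {
    warning("normal approximation is doubtful: n*p0 or n*(1-p0) below 5")
  }
  phat <- survivors / n
  z <- (phat - p0) / sqrt(p0 * (1 - p0) / n)
  p <- stats::pnorm(z, lower.tail = FALSE)
  list(z = z, p = p, estimate = phat, n = n, p0 = p0)
}

#' Four-group pharmacogenomic survival study
#'
#' Splits the merged cohort into the four cells of carrier status by drug
#' and tests each cell's survival rate one-sided against the untreated
#' baseline `p0 = 0.5` at level `alpha` (default 0.01). Carrier status is
#' derived from the pharmacogenomic genotype column (dosage `>= 1`), not
#' from any clinical field, so the genomic table stays causal for the
#' study. A carrier-by-drug-by-survival contingency table (the tabular
#' equivalent of a treatment-outcome flow diagram) is attached. Each of
#' the four cells is an independent test; no multiple-testing correction
#' is applied.
#'
#' @param merged A `merged_table` (or data frame).
#' @param pgx_column Name of the genotype/dosage column encoding the
#'   pharmacogenomic site (e.g. `"chr1:500000:A>G:GT"`); genotype strings
#'   are accepted.
#' @param alpha Significance level (default 0.01).
#' @param drug_col,survived_col Column names for the assigned drug and
#'   the survival outcome.
#' @param p0 Null survival proportion (default 0.5).
#' @return A `pgx_study` object: `results` data frame (one row per
#'   carrier-by-drug cell with `n`, `survivors`, `z`, `p`, `significant`,
#'   `testable`), `contingency` table and `alpha`.
#' @export
pgx_study <- function(merged, pgx_column, alpha = 0.01,
                      drug_col = "medication_1", survived_col = "survived",
                      p0 = 0.5) {
  df <- as.data.frame(merged)
  for (nm in c(pgx_column, drug_col, survived_col)) {
    if (!nm %in% names(df)) stop("merged table lacks column '", nm, "'")
  }
  g <- df[[pgx_column]]
  if (is.character(g)) g <- gt_dosage(g)
  carrier <- g >= 1
  drug <- as.character(df[[drug_col]])
  survived <- as.logical(df[[survived_col]])

  cells <- expand.grid(carrier = c(FALSE, TRUE),
                       drug = sort(unique(drug[!is.na(drug)])),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- !is.na(drug) & carrier == cells$carrier[i] & drug == cells$drug[i]
    n <- sum(sel)
    surv <- sum(survived[sel])
    if (n == 0L) {
      return(data.frame(carrier = cells$carrier[i], drug = cells$drug[i],
                        n = 0L, survivors = 0L, rate = NA_real_,
                        z = NA_real_, p = NA_real_, significant = FALSE,
                        testable = FALSE, stringsAsFactors = FALSE))
    }
    zt <- suppressWarnings(ztest_survival(surv, n, p0))
    data.frame(carrier = cells$carrier[i], drug = cells$drug[i], n = n,
               survivors = surv, rate = zt$estimate, z = zt$z, p = zt$p,
               significant = zt$p < alpha, testable = TRUE,
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  contingency <- table(
    carrier = factor(carrier, c(FALSE, TRUE), c("no variant", "variant")),
    drug = drug,
    outcome = factor(survived, c(TRUE, FALSE), c("survived", "died"))
  )
  structure(list(results = results, contingency = contingency,
                 alpha = alpha, p0 = p0),
            class = "pgx_study")
}

#' @export
print.pgx_study <- function(x, ...) {
  cat(sprintf("Pharmacogenomic survival study (one-sided z-test vs p0 = %g, alpha = %g)\n\n",
              x$p0, x$alpha))
  res <- x$results
  res$p <- signif(res$p, 4)
  res$z <- round(res$z, 3)
  res$rate <- round(res$rate, 4)
  print(res, row.names = FALSE)
  cat("\nTreatment-outcome counts:\n")
  print(stats::ftable(x$contingency))
  invisible(x)
}
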