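#' Merge per-patient variant records into one site-by-patient call table
#'
#' Takes the union of sites over all patients, keyed by
#' `(chrom, pos, ref, alt)`. Patients without a call at a site hold an
#' explicit missing call (not a zero-filled one), so missingness stays
#' visible until [impute_missing()] runs. Per-site allele frequency is
#' taken from the first record that carries one; sites with no `AF`
#' anywhere are assigned the cohort alternate-allele frequency computed
#' from the called genotypes (logged).
#'
#' @param tables Named list; one element per patient (names are patient
#'   ids), each a list of biallelic, normalized [variant_record()]s with
#'   exactly one call each.
#' @return A `call_table`: list with `sites` (data frame with `chrom`,
#'   `pos`, `ref`, `alt`, `af`, `key`) and site-by-patient matrices `gt`
#'   (genotype strings), `dp`, `pl` (comma-joined strings) and `imputed`.
#' @export
merge_samples <- function(tables) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("tables must be a named list of per-patient record lists")
  }
  if (anyDuplicated(names(tables))) {
    stop("duplicate patient id in merge_samples input: ",
         paste(unique(names(tables)[duplicated(names(tables))]), collapse = ", "))
  }
  patients <- names(tables)

  recs <- list()
  for (p in patients) {
    for (r in tables[[p]]) {
      stopifnot(inherits(r, "variant_record"))
      if (length(r$alts) != 1L) {
        stop("merge_samples requires biallelic records (run split_multiallelic)")
      }
      if (length(r$calls) != 1L) {
        stop("each per-patient record must carry exactly one sample call")
      }
      k <- site_key(r$chrom, r$pos, r$ref, r$alts[1])
      if (is.null(recs[[k]])) {
        recs[[k]] <- list(chrom = r$chrom, pos = r$pos, ref = r$ref,
                          alt = r$alts[1], af = r$af[1], calls = list())
      } else if (is.na(recs[[k]]$af) && !is.na(r$af[1])) {
        recs[[k]]$af <- r$af[1]
      }
      if (!is.null(recs[[k]]$calls[[p]])) {
        stop("duplicate call for patient ", p, " at site ", k)
      }
      recs[[k]]$calls[[p]] <- r$calls[[1]]
    }
  }

  sites <- data.frame(
    chrom = vapply(recs, `[[`, character(1), "chrom"),
    pos = vapply(recs, `[[`, integer(1), "pos"),
    ref = vapply(recs, `[[`, character(1), "ref"),
    alt = vapply(recs, `[[`, character(1), "alt"),
    af = vapply(recs, `[[`, numeric(1), "af"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  ord <- order(sites$chrom, sites$pos, sites$ref, sites$alt)
  sites <- sites[ord, , drop = FALSE]
  recs <- recs[ord]
  sites$key <- site_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  rownames(sites) <- NULL

  n_s <- nrow(sites); n_p <- length(patients)
  gt <- matrix(NA_character_, n_s, n_p, dimnames = list(sites$key, patients))
  dp <- matrix(NA_real_, n_s, n_p, dimnames = dimnames(gt))
  pl <- matrix(NA_character_, n_s, n_p, dimnames = dimnames(gt))
  imputed <- matrix(FALSE, n_s, n_p, dimnames = dimnames(gt))
  for (i in seq_len(n_s)) {
    for (p in names(recs[[i]]$calls)) {
      cl <- recs[[i]]$calls[[p]]
      if (!is_missing_token(cl$gt)) gt[i, p] <- cl$gt
      if (!is.na(cl$dp)) dp[i, p] <- cl$dp
      if (!is.null(cl$pl)) pl[i, p] <- paste(cl$pl, collapse = ",")
      imputed[i, p] <- isTRUE(cl$imputed)
    }
  }

  # AF fallback: cohort alt-allele frequency from called genotypes
  for (i in which(is.na(sites$af))) {
    dos <- gt_dosage(gt[i, ])
    called <- !is.na(dos)
    if (any(called)) {
      sites$af[i] <- sum(dos[called]) / (2 * sum(called))
      vlog("AF absent at %s: recomputed cohort frequency %.4f",
           sites$key[i], sites$af[i])
    }
  }

  structure(list(sites = sites, gt = gt, dp = dp, pl = pl, imputed = imputed),
            class = "call_table")
}

#' @export
print.call_table <- function(x, ...) {
  cat(sprintf("<call_table> %d sites x %d patients; %d missing call%s, %d imputed\n",
              nrow(x$sites), ncol(x$gt), sum(is.na(x$gt)),
              if (sum(is.na(x$gt)) == 1L) "" else "s", sum(x$imputed)))
  invisible(x)
}

#' Count of missing genotype calls in a call table
#' @param table A `call_table`.
#' @return Integer count of site-by-patient cells without a genotype.
#' @export
n_missing_calls <- function(table) {
  stopifnot(inherits(table, "call_table"))
  sum(is.na(table$gt))
}

#' Impute missing calls as average-quality reference calls
#'
#' Plain VCFs only report confidently called variants, so a patient with
#' no entry at a merged site most plausibly matched the reference there.
#' Each missing call is therefore replaced by a homozygous-reference call
#' of that patient's average quality and depth: `GT = 0/0`,
#' `DP = round(mean DP over the patient's called sites)` and
#' `PL = [0, g, 2g]` with `g = round(mean genotype quality)`, genotype
#' quality being the second-smallest PL entry of a called site. Calls that
#' were present but lacked DP or PL have just those components filled from
#' the same per-patient means (genotype kept, `imputed` flag not set).
#'
#' @param table A `call_table` from [merge_samples()].
#' @return The table with no missing entries; filled calls flagged
#'   `imputed`.
#' @export
impute_missing <- function(table) {
  stopifnot(inherits(table, "call_table"))
  out <- table
  for (p in colnames(table$gt)) {
    called <- !is.na(table$gt[, p])
    if (!any(called)) {
      stop("cannot impute for patient ", p, ": zero called sites")
    }
    dps <- table$dp[called, p]
    if (all(is.na(dps))) {
      stop("cannot impute for patient ", p, ": no called site has DP")
    }
    dp_imp <- round(mean(dps, na.rm = TRUE))
    gqs <- vapply(table$pl[called, p],
                  function(s) pl_gq(parse_pl(s)), numeric(1), USE.NAMES = FALSE)
    if (all(is.na(gqs))) {
      stop("cannot impute for patient ", p, ": no called site has PL")
    }
    g <- round(mean(gqs, na.rm = TRUE))
    pl_imp <- paste(c(0, g, 2 * g), collapse = ",")

    miss <- is.na(table$gt[, p])
    out$gt[miss, p] <- "0/0"
    out$dp[miss, p] <- dp_imp
    out$pl[miss, p] <- pl_imp
    out$imputed[miss, p] <- TRUE
    # component-missing fills on otherwise called sites
    out$dp[called & is.na(table$dp[, p]), p] <- dp_imp
    out$pl[called & is.na(table$pl[, p]), p] <- pl_imp
  }
  out
}

#' Dosage matrix of a call table
#'
#' @param table A `call_table`.
#' @return Numeric matrix (sites x patients) of alt-allele dosages 0/1/2
#'   (`NA` where the genotype is missing).
#' @export
dosage_matrix <- function(table) {
  stopifnot(inherits(table, "call_table"))
  d <- apply(table$gt, 2, gt_dosage)
  if (is.null(dim(d))) d <- matrix(d, nrow = nrow(table$sites))
  dimnames(d) <- dimnames(table$gt)
  d
}

#' Subset a call table to selected sites
#' @param table A `call_table`.
#' @param idx Integer site indices (rows of `table$sites`) to keep.
#' @return The subset `call_table`.
#' @export
subset_sites <- function(table, idx) {
  stopifnot(inherits(table, "call_table"))
  out <- table
  out$sites <- table$sites[idx, , drop = FALSE]
  rownames(out$sites) <- NULL
  for (f in c("gt", "dp", "pl", "imputed")) {
    out[[f]] <- table[[f]][idx, , drop = FALSE]
  }
  out
}
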