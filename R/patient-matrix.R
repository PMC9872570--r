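#' Transpose a call table into a patient-by-feature genomic matrix
#'
#' Each retained variant contributes exactly four columns named
#' `"<chrom>:<pos>:<ref>><alt>:<field>"` for the fields `GT` (encoded as
#' alt-allele dosage 0/1/2), `AF` (the site allele frequency, repeated for
#' every patient), `DP` and `PL` (comma-joined phred likelihood string).
#' One row per patient. The table must be fully imputed first; the imputed
#' flags travel as an attribute and survive the TSV round trip in
#' companion columns.
#'
#' @param table A fully imputed `call_table` (see [impute_missing()]).
#' @return A data frame of class `patient_matrix` with column `mrn`
#'   followed by the per-variant feature columns; attributes `sites`
#'   (site data frame) and `imputed` (patient-by-site logical matrix).
#' @export
to_patient_matrix <- function(table) {
  stopifnot(inherits(table, "call_table"))
  if (any(is.na(table$gt))) {
    stop("call table still has missing genotypes; run impute_missing first")
  }
  patients <- colnames(table$gt)
  keys <- table$sites$key
  out <- data.frame(mrn = patients, stringsAsFactors = FALSE)
  for (i in seq_along(keys)) {
    out[[paste0(keys[i], ":GT")]] <- as.numeric(gt_dosage(table$gt[i, ]))
    out[[paste0(keys[i], ":AF")]] <- rep(table$sites$af[i], length(patients))
    out[[paste0(keys[i], ":DP")]] <- as.numeric(table$dp[i, ])
    out[[paste0(keys[i], ":PL")]] <- as.character(table$pl[i, ])
  }
  rownames(out) <- NULL
  attr(out, "sites") <- table$sites
  attr(out, "imputed") <- t(table$imputed)
  class(out) <- c("patient_matrix", "data.frame")
  out
}

#' Rebuild the site-major call table from a patient matrix
#'
#' Inverse of [to_patient_matrix()] on the shared fields: dosages become
#' unphased genotypes (`0/0`, `0/1`, `1/1`), so the round trip is lossless
#' up to genotype phase and the imputed flag (which is carried by the
#' matrix attribute when present).
#'
#' @param pm A `patient_matrix`.
#' @return A `call_table`.
#' @export
matrix_to_call_table <- function(pm) {
  stopifnot(inherits(pm, "patient_matrix"))
  feat <- setdiff(names(pm), "mrn")
  keys <- unique(sub(":(GT|AF|DP|PL)$", "", feat))
  parts <- regmatches(keys, regexec("^(.+):([0-9]+):([ACGTN]+)>([ACGTN]+)$", keys))
  bad <- vapply(parts, length, integer(1)) != 5L
  if (any(bad)) stop("unparseable feature column key: ", keys[bad][1])
  sites <- data.frame(
    chrom = vapply(parts, `[`, character(1), 2),
    pos = as.integer(vapply(parts, `[`, character(1), 3)),
    ref = vapply(parts, `[`, character(1), 4),
    alt = vapply(parts, `[`, character(1), 5),
    af = vapply(keys, function(k) pm[[paste0(k, ":AF")]][1], numeric(1),
                USE.NAMES = FALSE),
    key = keys, row.names = NULL, stringsAsFactors = FALSE
  )
  patients <- pm$mrn
  n_s <- nrow(sites)
  gt <- matrix(NA_character_, n_s, length(patients),
               dimnames = list(keys, patients))
  dp <- matrix(NA_real_, n_s, length(patients), dimnames = dimnames(gt))
  pl <- matrix(NA_character_, n_s, length(patients), dimnames = dimnames(gt))
  for (i in seq_len(n_s)) {
    dos <- pm[[paste0(keys[i], ":GT")]]
    gt[i, ] <- c("0/0", "0/1", "1/1")[dos + 1L]
    dp[i, ] <- pm[[paste0(keys[i], ":DP")]]
    pl[i, ] <- pm[[paste0(keys[i], ":PL")]]
  }
  imp <- attr(pm, "imputed")
  imputed <- if (!is.null(imp)) t(imp) else
    matrix(FALSE, n_s, length(patients), dimnames = dimnames(gt))
  structure(list(sites = sites, gt = gt, dp = dp, pl = pl, imputed = imputed),
            class = "call_table")
}

#' @export
print.patient_matrix <- function(x, ...) {
  cat(sprintf("<patient_matrix> %d patients x %d variant features (%d sites)\n",
              nrow(x), ncol(x) - 1L, (ncol(x) - 1L) %/% 4L))
  NextMethod()
}

#' Write/read a patient genomic matrix as TSV
#'
#' Tab-separated export with a header row. Imputed flags are preserved in
#' one companion `...:IMPUTED` column (0/1) per site. The round trip is
#' exact: genotype-likelihood strings verbatim, numerics as printed.
#'
#' @param pm A `patient_matrix`.
#' @param path Output/input file path.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns the `patient_matrix`.
#' @export
write_matrix_tsv <- function(pm, path) {
  stopifnot(inherits(pm, "patient_matrix"))
  out <- as.data.frame(pm)
  imp <- attr(pm, "imputed")
  if (!is.null(imp) && ncol(imp)) {
    for (k in colnames(imp)) out[[paste0(k, ":IMPUTED")]] <- as.integer(imp[, k])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("TSV file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("TSV format error: empty file")
  ncols <- vapply(strsplit(lines, "\t", fixed = TRUE), length, integer(1))
  if (any(ncols != ncols[1])) {
    stop("TSV format error: line ", which(ncols != ncols[1])[1],
         " has ", ncols[ncols != ncols[1]][1], " columns, expected ", ncols[1])
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = NA)
  # PL columns must stay character even when they look numeric-ish
  for (nm in grep(":PL$", names(df), value = TRUE)) {
    df[[nm]] <- as.character(df[[nm]])
  }
  df$mrn <- as.character(df$mrn)
  imp_cols <- grep(":IMPUTED$", names(df), value = TRUE)
  imp <- NULL
  if (length(imp_cols)) {
    imp <- sapply(imp_cols, function(nm) df[[nm]] == 1L)
    if (is.null(dim(imp))) imp <- matrix(imp, nrow = nrow(df))
    colnames(imp) <- sub(":IMPUTED$", "", imp_cols)
    rownames(imp) <- df$mrn
    df <- df[, setdiff(names(df), imp_cols), drop = FALSE]
  }
  class(df) <- c("patient_matrix", "data.frame")
  attr(df, "imputed") <- imp
  ct <- try(matrix_to_call_table(df), silent = TRUE)
  if (!inherits(ct, "try-error")) attr(df, "sites") <- ct$sites
  df
}
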