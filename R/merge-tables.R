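#' Merge the clinical table with the patient genomic matrix
#'
#' Inner join on the medical record number. Patients present in only one
#' input are listed in the attached drop report rather than silently
#' discarded; non-key column name collisions are resolved by prefixing the
#' source (`clinical_` / `genomic_`).
#'
#' @param clinical A `clinical_table` (or any data frame) with unique
#'   `mrn` values.
#' @param genomic A `patient_matrix` (or data frame) with unique `mrn`
#'   values.
#' @param key Join column name, default `"mrn"`.
#' @return A `merged_table` data frame; attribute `drop_report` is a list
#'   with `clinical_only` and `genomic_only` key vectors.
#' @export
merge_tables <- function(clinical, genomic, key = "mrn") {
  clinical <- as.data.frame(clinical)
  genomic <- as.data.frame(genomic)
  for (nm in c("clinical", "genomic")) {
    tab <- get(nm)
    if (!key %in% names(tab)) stop(nm, " table lacks join key column '", key, "'")
    if (anyDuplicated(tab[[key]])) {
      stop("duplicate ", key, " in ", nm, " table: ",
           paste(unique(tab[[key]][duplicated(tab[[key]])]), collapse = ", "))
    }
  }
  shared <- setdiff(intersect(names(clinical), names(genomic)), key)
  if (length(shared)) {
    names(clinical)[match(shared, names(clinical))] <- paste0("clinical_", shared)
    names(genomic)[match(shared, names(genomic))] <- paste0("genomic_", shared)
  }
  out <- merge(clinical, genomic, by = key, sort = TRUE)
  drop <- list(
    clinical_only = sort(setdiff(clinical[[key]], genomic[[key]])),
    genomic_only = sort(setdiff(genomic[[key]], clinical[[key]]))
  )
  if (length(drop$clinical_only) || length(drop$genomic_only)) {
    vlog("merge dropped %d clinical-only and %d genomic-only patients",
         length(drop$clinical_only), length(drop$genomic_only))
  }
  attr(out, "drop_report") <- drop
  class(out) <- c("merged_table", "data.frame")
  out
}

#' Encode merged-table columns as a numeric feature matrix
#'
#' Genotype columns become alt-allele dosage (0/1/2; genotype strings such
#' as `"0/1"` are accepted), categorical columns are one-hot encoded, and
#' numeric columns are z-score standardized. Constant columns carry no
#' information for clustering and are dropped (logged). The output has no
#' missing values: rows with `NA` in a configured column raise an error so
#' imputation problems surface early.
#'
#' @param merged A `merged_table` (or data frame).
#' @param features Named list configuring which columns enter:
#'   `genotype`, `categorical`, `numeric` (character vectors of column
#'   names). When `NULL`, a default is derived: all `...:GT` columns as
#'   genotype, `gender` and `drug`-like columns as categorical, `age` as
#'   numeric, when present.
#' @return Numeric matrix, rows named by `mrn` when available; attribute
#'   `dropped` lists constant columns removed.
#' @export
encode_features <- function(merged, features = NULL) {
  df <- as.data.frame(merged)
  if (is.null(features)) {
    features <- list(
      genotype = grep(":GT$", names(df), value = TRUE),
      categorical = intersect(c("gender", "medication_1"), names(df)),
      numeric = intersect("age", names(df))
    )
  }
  missing_cols <- setdiff(unlist(features), names(df))
  if (length(missing_cols)) {
    stop("feature config names absent columns: ",
         paste(missing_cols, collapse = ", "))
  }
  cols <- list()
  for (nm in features$genotype %||% character(0)) {
    v <- df[[nm]]
    if (is.character(v)) v <- gt_dosage(v)
    cols[[nm]] <- as.numeric(v)
  }
  for (nm in features$categorical %||% character(0)) {
    v <- as.character(df[[nm]])
    for (lev in sort(unique(v[!is.na(v)]))) {
      cols[[paste0(nm, "=", lev)]] <- as.numeric(v == lev)
    }
  }
  for (nm in features$numeric %||% character(0)) {
    v <- df[[nm]]
    if (!is.numeric(v)) stop("non-encodable column type for '", nm, "'")
    cols[[nm]] <- v
  }
  if (!length(cols)) stop("feature config selected no columns")
  X <- do.call(cbind, cols)
  rownames(X) <- if ("mrn" %in% names(df)) df$mrn else NULL
  if (anyNA(X)) {
    bad <- colnames(X)[colSums(is.na(X)) > 0]
    stop("missing values in feature columns: ", paste(bad, collapse = ", "))
  }
  keep <- apply(X, 2, function(v) stats::var(v) > 0)
  dropped <- colnames(X)[!keep]
  if (length(dropped)) {
    vlog("dropping constant feature column(s): %s", paste(dropped, collapse = ", "))
  }
  X <- X[, keep, drop = FALSE]
  # z-score standardization of the numeric block (dosage/one-hot included:
  # clustering distances then weight all features comparably)
  nums <- intersect(colnames(X), features$numeric %||% character(0))
  for (nm in nums) X[, nm] <- (X[, nm] - mean(X[, nm])) / stats::sd(X[, nm])
  attr(X, "dropped") <- dropped
  X
}
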