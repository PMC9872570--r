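#' Variant records and per-sample calls
#'
#' A `variant_record` is the genomic atom of the pipeline: one VCF site with
#' its alternate alleles, per-alt allele frequencies and per-sample calls.
#' Coordinates are 1-based inclusive, matching VCF.
#'
#' @param chrom Contig name.
#' @param pos 1-based position, `>= 1`.
#' @param ref Reference allele, non-empty string over `A,C,G,T,N`.
#' @param alts Character vector of alternate alleles (same alphabet).
#' @param af Numeric vector of per-alt allele frequencies in `[0, 1]`;
#'   must have one entry per alt. `NA` marks an unknown frequency.
#' @param calls Named list of [sample_call()] objects, one per sample.
#' @return An object of class `variant_record`.
#' @export
variant_record <- function(chrom, pos, ref, alts, af = rep(NA_real_, length(alts)),
                           calls = list()) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("variant position must be >= 1")
  alts <- as.character(alts)
  if (!nzchar(ref) || !all(nzchar(alts))) {
    stop("ref and alt alleles must be non-empty")
  }
  ok <- grepl("^[ACGTN]+$", c(ref, alts))
  if (!all(ok)) stop("alleles must be strings over {A,C,G,T,N}")
  if (length(af) != length(alts)) {
    stop("length(af) must equal length(alts)")
  }
  af <- as.numeric(af)
  if (any(!is.na(af) & (af < 0 | af > 1))) stop("allele frequencies must lie in [0,1]")
  if (length(calls) && is.null(names(calls))) stop("calls must be named by sample id")
  # PL sanity is only defined for biallelic records (3 genotype likelihoods)
  if (length(alts) == 1L) {
    for (cl in calls) {
      if (!is.null(cl$pl) && !all(is.na(cl$pl))) {
        if (length(cl$pl) != 3L) stop("biallelic PL must have exactly 3 entries")
        if (any(cl$pl < 0) || min(cl$pl) != 0) {
          stop("PL entries must be >= 0 with min(PL) == 0")
        }
      }
    }
  }
  structure(
    list(chrom = chrom, pos = pos, ref = ref, alts = alts, af = af, calls = calls),
    class = "variant_record"
  )
}

#' @param gt Genotype string such as `"0/1"` (phased `"0|1"` accepted), or
#'   `NA` when the genotype is missing.
#' @param dp Read depth (`>= 0`) or `NA`.
#' @param pl Integer triple of phred-scaled genotype likelihoods
#'   (`min(pl) == 0` for a biallelic site), or `NULL`/`NA` when missing.
#' @param imputed Logical flag marking calls filled in by [impute_missing()].
#' @rdname variant_record
#' @export
sample_call <- function(gt = NA_character_, dp = NA_integer_, pl = NULL,
                        imputed = FALSE) {
  if (is_missing_token(gt)) gt <- NA_character_
  if (!is.null(pl) && all(is.na(pl))) pl <- NULL
  dp <- suppressWarnings(as.integer(dp))
  if (!is.na(dp) && dp < 0L) stop("DP must be >= 0")
  list(gt = gt, dp = dp, pl = if (is.null(pl)) NULL else as.numeric(pl),
       imputed = isTRUE(imputed))
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("<variant_record> %s:%d %s>%s (af=%s; %d sample%s)\n",
              x$chrom, x$pos, x$ref, paste(x$alts, collapse = ","),
              paste(signif(x$af, 3), collapse = ","),
              length(x$calls), if (length(x$calls) == 1L) "" else "s"))
  invisible(x)
}

#' Alternate-allele dosage of a genotype string
#'
#' Counts the alt alleles (allele index 1) in a biallelic genotype such as
#' `"0/1"`; phase separators `/` and `|` are equivalent. Missing genotypes
#' give `NA`.
#'
#' @param gt Character vector of genotype strings.
#' @return Integer vector of dosages in `{0, 1, 2}` (or `NA`).
#' @export
gt_dosage <- function(gt) {
  vapply(gt, function(g) {
    if (is_missing_token(g)) return(NA_integer_)
    toks <- strsplit(g, "[/|]")[[1]]
    if (any(toks == ".")) return(NA_integer_)
    sum(toks == "1")
  }, integer(1), USE.NAMES = FALSE)
}

# canonical "chrom:pos:ref>alt" key for a biallelic site
site_key <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d:%s>%s", chrom, as.integer(pos), ref, alt)
}

# parse "a,b,c" PL strings into numeric vectors (NULL when missing)
parse_pl <- function(x) {
  if (is_missing_token(x)) return(NULL)
  as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
}

# genotype quality = second-smallest PL entry (phred distance to the
# next-most-likely genotype)
pl_gq <- function(pl) {
  if (is.null(pl) || length(pl) < 2L) return(NA_real_)
  sort(pl)[2L]
}
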