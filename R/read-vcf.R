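#' Read a VCF file into variant records
#'
#' Parses a VCF 4.2 file (plain or gzipped) into a list of
#' [variant_record()] objects, one per data line. `GT`, `DP` and `PL` are
#' extracted per sample; the per-alt allele frequency comes from the INFO
#' `AF` field when present. Missing FORMAT values are flagged missing —
#' never zero-filled — so that downstream imputation can distinguish an
#' uncalled site from a homozygous-reference call.
#'
#' Field extraction is delegated to \pkg{vcfR}; a light structural pre-scan
#' of the raw lines reports malformed headers or data lines with their line
#' number before parsing starts.
#'
#' @param path Path to a `.vcf` or `.vcf.gz` file.
#' @return A list of `variant_record` objects (empty list for a header-only
#'   file).
#' @seealso [split_multiallelic()], [normalize_variant()], [merge_samples()]
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^##fileformat=VCF", lines[1])) {
    stop("malformed VCF header at line 1: expected '##fileformat=VCF...'")
  }
  chrom_at <- grep("^#CHROM\t", lines)
  if (length(chrom_at) != 1L) {
    stop("malformed VCF header: expected exactly one #CHROM line, found ",
         length(chrom_at))
  }
  header_fields <- strsplit(lines[chrom_at], "\t", fixed = TRUE)[[1]]
  if (length(header_fields) < 8L) {
    stop("malformed VCF header at line ", chrom_at,
         ": fewer than 8 columns in #CHROM line")
  }
  n_col <- length(header_fields)
  data_at <- setdiff(which(nzchar(lines)), grep("^#", lines))
  for (i in data_at) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != n_col) {
      stop(sprintf("malformed VCF data line %d: expected %d fields, found %d",
                   i, n_col, length(fields)))
    }
    if (!grepl("^[0-9]+$", fields[2])) {
      stop(sprintf("malformed VCF data line %d: POS '%s' is not a positive integer",
                   i, fields[2]))
    }
  }
  if (!length(data_at)) return(list())

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  n_rec <- nrow(fix)
  samples <- if (ncol(v@gt) > 1L) colnames(v@gt)[-1L] else character(0)
  af_str <- vcfR::extract.info(v, element = "AF")
  gt_mat <- if (length(samples)) vcfR::extract.gt(v, element = "GT") else NULL
  dp_mat <- if (length(samples)) {
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  } else NULL
  pl_mat <- if (length(samples)) vcfR::extract.gt(v, element = "PL") else NULL

  lapply(seq_len(n_rec), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    af <- if (is.na(af_str[i])) rep(NA_real_, length(alts)) else {
      suppressWarnings(as.numeric(strsplit(af_str[i], ",", fixed = TRUE)[[1]]))
    }
    if (length(af) != length(alts)) af <- rep(NA_real_, length(alts))
    calls <- stats::setNames(lapply(samples, function(s) {
      sample_call(
        gt = if (is.null(gt_mat)) NA_character_ else gt_mat[i, s],
        dp = if (is.null(dp_mat)) NA_integer_ else dp_mat[i, s],
        pl = if (is.null(pl_mat)) NULL else parse_pl(pl_mat[i, s])
      )
    }), samples)
    variant_record(
      chrom = unname(fix[i, "CHROM"]), pos = as.integer(fix[i, "POS"]),
      ref = unname(fix[i, "REF"]), alts = alts, af = af, calls = calls
    )
  })
}
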