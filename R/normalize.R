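#' Split a multi-allelic record into biallelic records
#'
#' Fixed-width tabulation of per-variant fields requires one alternate
#' allele per record, so a site with `k` alts becomes `k` biallelic
#' records. The per-alt allele frequency travels with its record. Genotype
#' allele indexes referring to the record's own alt are recoded to `1`;
#' indexes referring to any other alt are recoded to `0` (a lossy recode,
#' flagged on the output record and logged), so allele counts per record
#' stay interpretable as dosage of the focal alt. Biallelic input is
#' returned unchanged.
#'
#' Phred likelihoods of a multi-allelic call are subset to the genotypes
#' over `{ref, focal alt}` and re-anchored at zero; when the PL vector
#' length is inconsistent with the allele count it is dropped as missing.
#'
#' @param record A [variant_record()] with at least one alt.
#' @return List of biallelic `variant_record` objects, one per alt, in
#'   input alt order. Records whose genotypes lost non-focal alt alleles
#'   carry attribute `lossy_recode = TRUE`.
#' @export
split_multiallelic <- function(record) {
  stopifnot(inherits(record, "variant_record"))
  n_alt <- length(record$alts)
  if (n_alt < 1L) stop("record must have at least one alt allele")
  if (n_alt == 1L) return(list(record))

  n_allele <- n_alt + 1L
  g_expected <- n_allele * (n_allele + 1L) / 2L
  lapply(seq_len(n_alt), function(a) {
    lossy <- FALSE
    calls <- lapply(record$calls, function(cl) {
      gt <- cl$gt
      if (!is_missing_token(gt)) {
        sep <- if (grepl("|", gt, fixed = TRUE)) "|" else "/"
        toks <- strsplit(gt, "[/|]")[[1]]
        rec <- vapply(toks, function(t) {
          if (t == ".") return(".")
          ti <- as.integer(t)
          if (ti == a) "1" else {
            if (ti != 0L && ti != a) lossy <<- TRUE
            "0"
          }
        }, character(1))
        gt <- paste(rec, collapse = sep)
      }
      pl <- cl$pl
      if (!is.null(pl)) {
        if (length(pl) == g_expected) {
          # PL index of genotype (j,k), j<=k alleles, is k(k+1)/2 + j (0-based)
          idx <- c(1L, a * (a + 1L) / 2L + 1L, a * (a + 1L) / 2L + a + 1L)
          pl <- pl[idx]
          pl <- pl - min(pl)
        } else {
          pl <- NULL
        }
      }
      sample_call(gt = gt, dp = cl$dp, pl = pl, imputed = cl$imputed)
    })
    names(calls) <- names(record$calls)
    out <- variant_record(record$chrom, record$pos, record$ref,
                          record$alts[a], record$af[a], calls)
    if (lossy) {
      attr(out, "lossy_recode") <- TRUE
      vlog("lossy genotype recode at %s:%d alt %s (non-focal alt set to 0)",
           record$chrom, record$pos, record$alts[a])
    }
    out
  })
}

#' Reference sequence accessor
#'
#' Wraps a reference genome as a function `(chrom, start, end) -> string`.
#' Accepts a named character vector of contig sequences, a FASTA file path
#' (read through \pkg{Biostrings} when installed), or an existing accessor
#' function, which is returned as-is.
#'
#' @param reference Named character vector, FASTA path, or function.
#' @return A function `(chrom, start, end)` returning the reference bases.
#' @export
reference_accessor <- function(reference) {
  if (is.function(reference)) return(reference)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference) && is.null(names(reference))) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading a FASTA reference requires the Biostrings package")
    }
    seqs <- Biostrings::readDNAStringSet(reference)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    reference <- stats::setNames(as.character(seqs), names(seqs))
  }
  stopifnot(is.character(reference), !is.null(names(reference)))
  function(chrom, start, end) {
    if (!chrom %in% names(reference)) {
      stop("reference does not cover contig ", chrom)
    }
    if (start < 1L || end > nchar(reference[[chrom]])) {
      stop(sprintf("reference does not cover %s:%d-%d", chrom, start, end))
    }
    substr(reference[[chrom]], start, end)
  }
}

#' Left-align and trim a biallelic variant
#'
#' Returns the parsimonious, leftmost-aligned representation of an indel
#' (SNPs pass through unchanged): shared trailing bases are truncated
#' iteratively; whenever an allele empties, the preceding reference base is
#' prepended and the position decremented; finally shared leading bases are
#' trimmed while both alleles keep length at least 2. The returned edit is
#' equivalent to the input edit (applying either to the reference yields
#' the same alternate sequence) and the operation is idempotent.
#'
#' Without a reference the procedure degrades, with a warning, to parsimony
#' trimming only (no left shift is possible).
#'
#' @param record A biallelic [variant_record()].
#' @param reference Anything accepted by [reference_accessor()], or `NULL`.
#' @return A normalized `variant_record` with the same calls.
#' @export
normalize_variant <- function(record, reference = NULL) {
  stopifnot(inherits(record, "variant_record"))
  if (length(record$alts) != 1L) {
    stop("normalize_variant requires a biallelic record; run split_multiallelic first")
  }
  ref <- record$ref
  alt <- record$alts[1]
  pos <- record$pos

  if (is.null(reference)) {
    warning("no reference supplied: left-alignment skipped, parsimony trimming only")
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
    }
  } else {
    acc <- reference_accessor(reference)
    seen <- acc(record$chrom, pos, pos + nchar(ref) - 1L)
    if (!identical(seen, ref)) {
      stop(sprintf("REF allele '%s' disagrees with reference sequence '%s' at %s:%d",
                   ref, seen, record$chrom, pos))
    }
    repeat {
      if (nchar(ref) > 0L && nchar(alt) > 0L &&
          substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
        ref <- substr(ref, 1L, nchar(ref) - 1L)
        alt <- substr(alt, 1L, nchar(alt) - 1L)
      }
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos == 1L) {
          # contig start: no preceding base exists, so anchor on the base
          # following the allele instead (the leftmost representation)
          nxt <- acc(record$chrom, nchar(ref) + 1L, nchar(ref) + 1L)
          ref <- paste0(ref, nxt)
          alt <- paste0(alt, nxt)
          break
        }
        pre <- acc(record$chrom, pos - 1L, pos - 1L)
        ref <- paste0(pre, ref)
        alt <- paste0(pre, alt)
        pos <- pos - 1L
        next
      }
      if (substr(ref, nchar(ref), nchar(ref)) != substr(alt, nchar(alt), nchar(alt))) {
        break
      }
    }
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  variant_record(record$chrom, pos, ref, alt, record$af, record$calls)
}

#' Apply a biallelic edit to a reference sequence
#'
#' Utility used to check edit equivalence of variant representations:
#' substitutes `alt` for `ref` at `pos` in the contig sequence.
#'
#' @param seq Contig sequence (single string).
#' @param pos 1-based position of the edit.
#' @param ref,alt Reference and alternate alleles.
#' @return The edited sequence.
#' @export
apply_edit <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seq, 1L, pos - 1L), alt, substr(seq, pos + nchar(ref), nchar(seq)))
}
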