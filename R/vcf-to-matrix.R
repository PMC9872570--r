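#' Build the patient genomic matrix from per-patient VCFs
#'
#' One call chaining the variant-matrix stages: read each VCF, split
#' multi-allelic sites, normalize (left-align when a reference is given,
#' parsimony trimming otherwise), merge across patients, LD-prune on the
#' dosage matrix, impute missing calls and transpose to the patient
#' matrix.
#'
#' @param vcf_paths Character vector of per-patient VCF paths; patient
#'   ids default to the file base names unless the VCF's sample name is
#'   used (`ids = "sample"`).
#' @param reference Optional reference accepted by [reference_accessor()].
#' @param r2 LD pruning threshold; `NULL` disables pruning.
#' @param window,step LD pruning window parameters (see [ld_prune()]).
#' @param keep_sites Data frame of sites (chrom, pos, ref, alt) always
#'   retained through pruning, e.g. a designated pharmacogenomic site.
#' @param ids `"file"` (base name without extension) or `"sample"` (VCF
#'   sample column name).
#' @return A `patient_matrix`; attribute `n_pruned` records how many
#'   sites LD pruning removed.
#' @export
vcf_to_matrix <- function(vcf_paths, reference = NULL, r2 = 0.5,
                          window = 50L, step = 5L, keep_sites = NULL,
                          ids = c("file", "sample")) {
  ids <- match.arg(ids)
  tables <- list()
  for (path in vcf_paths) {
    recs <- read_vcf(path)
    pid <- if (ids == "file") {
      sub("\\.vcf(\\.gz)?$", "", basename(path))
    } else {
      if (!length(recs) || !length(names(recs[[1]]$calls))) {
        stop("cannot take patient id from sample column of ", path)
      }
      names(recs[[1]]$calls)[1]
    }
    recs <- unlist(lapply(recs, split_multiallelic), recursive = FALSE)
    recs <- lapply(recs, function(r) {
      if (is.null(reference)) {
        suppressWarnings(normalize_variant(r, NULL))
      } else {
        normalize_variant(r, reference)
      }
    })
    if (!is.null(tables[[pid]])) stop("duplicate patient id: ", pid)
    tables[[pid]] <- recs
  }
  ct <- merge_samples(tables)
  n_pruned <- 0L
  if (!is.null(r2) && nrow(ct$sites) > 1L) {
    keep <- ld_prune(dosage_matrix(ct), r2_threshold = r2,
                     window = window, step = step)
    if (!is.null(keep_sites)) {
      must <- which(ct$sites$chrom %in% keep_sites$chrom &
                      ct$sites$pos %in% keep_sites$pos)
      keep <- sort(union(keep, must))
    }
    n_pruned <- nrow(ct$sites) - length(keep)
    ct <- subset_sites(ct, keep)
  }
  ct <- impute_missing(ct)
  pm <- to_patient_matrix(ct)
  attr(pm, "n_pruned") <- n_pruned
  pm
}
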