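# Independent brute-force oracles and fixture builders. These deliberately
# use explicit-loop, definitional implementations so they share no code
# path with the package functions they check.

euclid <- function(a, b) sqrt(sum((a - b)^2))

# Pearson correlation from the raw-sum formula
brute_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  if (den == 0) return(NA_real_)
  num / den
}

brute_davies_bouldin <- function(X, labels) {
  levs <- sort(unique(labels))
  k <- length(levs)
  cents <- lapply(levs, function(l) colMeans(X[labels == l, , drop = FALSE]))
  S <- numeric(k)
  for (i in seq_len(k)) {
    pts <- X[labels == levs[i], , drop = FALSE]
    d <- 0
    for (r in seq_len(nrow(pts))) d <- d + euclid(pts[r, ], cents[[i]])
    S[i] <- d / nrow(pts)
  }
  total <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (j == i) next
      ratio <- (S[i] + S[j]) / euclid(cents[[i]], cents[[j]])
      if (ratio > worst) worst <- ratio
    }
    total <- total + worst
  }
  total / k
}

brute_calinski_harabasz <- function(X, labels) {
  n <- nrow(X)
  levs <- sort(unique(labels))
  k <- length(levs)
  grand <- colMeans(X)
  bss <- 0; wss <- 0
  for (l in levs) {
    pts <- X[labels == l, , drop = FALSE]
    cent <- colMeans(pts)
    bss <- bss + nrow(pts) * euclid(cent, grand)^2
    for (r in seq_len(nrow(pts))) wss <- wss + euclid(pts[r, ], cent)^2
  }
  (bss / (k - 1)) / (wss / (n - k))
}

brute_silhouette <- function(X, labels) {
  n <- nrow(X)
  levs <- sort(unique(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (!length(mates)) { s[i] <- 0; next }
    a <- mean(vapply(mates, function(j) euclid(X[i, ], X[j, ]), numeric(1)))
    b <- Inf
    for (l in setdiff(levs, own)) {
      others <- which(labels == l)
      bl <- mean(vapply(others, function(j) euclid(X[i, ], X[j, ]), numeric(1)))
      if (bl < b) b <- bl
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# random labeling with every cluster non-empty
random_labels <- function(n, k) {
  repeat {
    l <- sample.int(k, n, replace = TRUE)
    if (length(unique(l)) == k) return(l)
  }
}

# upper-tail standard-normal probability by numerical integration
normal_tail_oracle <- function(z) {
  stats::integrate(function(t) exp(-t^2 / 2) / sqrt(2 * pi), z, Inf,
                   rel.tol = 1e-14)$value
}

# exact central binomial interval at the given two-sided coverage
binom_interval <- function(n, p, coverage = 0.999) {
  a <- (1 - coverage) / 2
  c(stats::qbinom(a, n, p), stats::qbinom(1 - a, n, p))
}

# --- fixture builders -------------------------------------------------------

# a variant record with a single sample call
make_rec <- function(chrom = "chr1", pos, ref, alt, af = 0.2, gt = "0/1",
                     dp = 30L, pl = c(40, 0, 40), sample = "S1") {
  calls <- stats::setNames(list(sample_call(gt = gt, dp = dp, pl = pl)), sample)
  variant_record(chrom, pos, ref, alt, af, calls)
}

write_vcf_fixture <- function(lines, dir = tempdir()) {
  path <- tempfile("fix", tmpdir = dir, fileext = ".vcf")
  writeLines(lines, path)
  path
}

vcf_fixture_lines <- function(data_lines, sample = "S1") {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred likelihoods\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample), collapse = "\t"),
    data_lines)
}

# a minimal FHIR bundle in list form
make_bundle <- function(mrn, gender = "female", birth = "1970-01-01",
                        deceased = NULL, conditions = list(),
                        medications = character(0), observations = list(),
                        extra_entries = list()) {
  pat <- list(
    resourceType = "Patient", id = paste0("pat-", mrn),
    identifier = list(list(type = list(coding = list(list(code = "MR"))),
                           value = mrn)),
    gender = gender, birthDate = birth
  )
  if (!is.null(deceased)) pat$deceasedDateTime <- deceased
  subject <- list(reference = paste0("Patient/pat-", mrn))
  entries <- list(list(fullUrl = paste0("urn:uuid:pat-", mrn), resource = pat))
  ci <- 0
  for (cond in conditions) {
    ci <- ci + 1
    entries[[length(entries) + 1L]] <- list(resource = list(
      resourceType = "Condition", id = sprintf("cond-%s-%d", mrn, ci),
      subject = subject,
      code = list(coding = list(list(code = cond$code))),
      onsetDateTime = cond$onset %||% "2021-01-01T00:00:00Z"))
  }
  mi <- 0
  for (med in medications) {
    mi <- mi + 1
    entries[[length(entries) + 1L]] <- list(resource = list(
      resourceType = "MedicationRequest", id = sprintf("med-%s-%d", mrn, mi),
      subject = subject,
      medicationCodeableConcept = list(text = med),
      authoredOn = sprintf("2021-02-%02dT00:00:00Z", mi)))
  }
  oi <- 0
  for (ob in observations) {
    oi <- oi + 1
    entries[[length(entries) + 1L]] <- list(resource = list(
      resourceType = "Observation", id = sprintf("obs-%s-%d", mrn, oi),
      subject = subject,
      code = list(coding = list(list(code = ob$code))),
      valueQuantity = list(value = ob$value)))
  }
  entries <- c(entries, extra_entries)
  list(resourceType = "Bundle", type = "collection", entry = entries)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random reference sequence with embedded repeats, plus a denormalized
# indel representation that is edit-equivalent to a parsimonious one
random_indel_case <- function() {
  motif <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1), replace = TRUE),
                 collapse = "")
  seq <- paste0(
    paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = ""),
    paste(rep(motif, sample(3:6, 1)), collapse = ""),
    paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE), collapse = "")
  )
  n <- nchar(seq)
  pos <- sample(2:(n - 8), 1)
  if (stats::runif(1) < 0.5) {
    len <- sample(1:3, 1)                      # deletion
    ref <- substr(seq, pos, pos + len)
    alt <- substr(seq, pos, pos)
  } else {
    ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1), replace = TRUE),
                 collapse = "")                # insertion
    ref <- substr(seq, pos, pos)
    alt <- paste0(ref, ins)
  }
  # denormalize: append the next few reference bases to both alleles
  pad <- sample(0:3, 1)
  if (pad > 0 && pos + nchar(ref) + pad - 1L <= n) {
    tail_seq <- substr(seq, pos + nchar(ref), pos + nchar(ref) + pad - 1L)
    ref <- paste0(ref, tail_seq)
    alt <- paste0(alt, tail_seq)
  }
  list(seq = seq, pos = pos, ref = ref, alt = alt)
}
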