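# VCF reading, normalization, LD pruning, merging, imputation, transpose

test_that("read_vcf maps fields, flags missing calls, handles empty files", {
  path <- write_vcf_fixture(vcf_fixture_lines(
    c("chr1\t100\t.\tA\tG\t50\tPASS\tAF=0.2\tGT:DP:PL\t0/1:30:40,0,40",
      "chr1\t200\t.\tC\tT\t50\tPASS\tAF=0.1\tGT:DP:PL\t./.:.:.")))
  recs <- read_vcf(path)
  expect_length(recs, 2L)
  r <- recs[[1]]
  expect_equal(r$chrom, "chr1")
  expect_equal(r$pos, 100L)
  expect_equal(r$ref, "A")
  expect_equal(r$alts, "G")
  expect_equal(r$af, 0.2)
  expect_equal(r$calls$S1$gt, "0/1")
  expect_equal(r$calls$S1$dp, 30L)
  expect_equal(r$calls$S1$pl, c(40, 0, 40))
  # "./." stays missing, never zero-filled, and is not flagged imputed
  miss <- recs[[2]]$calls$S1
  expect_true(is.na(miss$gt))
  expect_true(is.na(miss$dp))
  expect_null(miss$pl)
  expect_false(miss$imputed)

  empty <- write_vcf_fixture(vcf_fixture_lines(character(0)))
  expect_identical(read_vcf(empty), list())
})

test_that("read_vcf names the offending line in parse errors", {
  bad_data <- write_vcf_fixture(vcf_fixture_lines(
    c("chr1\t100\t.\tA\tG\t50\tPASS\tAF=0.2\tGT:DP:PL\t0/1:30:40,0,40",
      "chr1\t200\t.\tC\tT\t50\tPASS")))
  expect_error(read_vcf(bad_data), "line 9")
  bad_pos <- write_vcf_fixture(vcf_fixture_lines(
    "chr1\tXYZ\t.\tA\tG\t50\tPASS\tAF=0.2\tGT:DP:PL\t0/1:30:40,0,40"))
  expect_error(read_vcf(bad_pos), "line 8.*POS")
  no_header <- write_vcf_fixture(c("chr1\t100\t.\tA\tG\t50\tPASS\tAF=0.2"))
  expect_error(read_vcf(no_header), "line 1")
})

test_that("split_multiallelic recodes genotypes and carries per-alt AF", {
  bi <- make_rec(pos = 100, ref = "A", alt = "G")
  expect_identical(split_multiallelic(bi), list(bi))

  multi <- variant_record("chr1", 100, "A", c("G", "T"), af = c(0.1, 0.3),
                          calls = list(S1 = sample_call("1/2", 30L)))
  out <- split_multiallelic(multi)
  expect_length(out, 2L)
  expect_equal(out[[1]]$alts, "G")
  expect_equal(out[[1]]$af, 0.1)
  expect_equal(out[[1]]$calls$S1$gt, "1/0")
  expect_equal(out[[2]]$alts, "T")
  expect_equal(out[[2]]$af, 0.3)
  expect_equal(out[[2]]$calls$S1$gt, "0/1")
  expect_true(isTRUE(attr(out[[1]], "lossy_recode")))

  homref <- variant_record("chr1", 100, "A", c("G", "T"), af = c(0.1, 0.3),
                           calls = list(S1 = sample_call("0/0")))
  out0 <- split_multiallelic(homref)
  expect_equal(out0[[1]]$calls$S1$gt, "0/0")
  expect_equal(out0[[2]]$calls$S1$gt, "0/0")
})

test_that("split_multiallelic conserves total alt-allele count for any genotype", {
  set.seed(1)
  for (rep in 1:50) {
    n_alt <- sample(2:4, 1)
    toks <- sample(0:n_alt, 2, replace = TRUE)
    gt <- paste(toks, collapse = "/")
    rec <- variant_record("chr1", 100, "A",
                          c("G", "T", "C", "N")[seq_len(n_alt)],
                          af = rep(0.1, n_alt),
                          calls = list(S1 = sample_call(gt)))
    out <- split_multiallelic(rec)
    dosages <- vapply(out, function(r) gt_dosage(r$calls$S1$gt), integer(1))
    expect_equal(sum(dosages), sum(toks > 0))
  }
})

test_that("split_multiallelic subsets PL to the focal-alt triple", {
  # 3 alleles -> PL over genotypes 0/0,0/1,1/1,0/2,1/2,2/2
  rec <- variant_record("chr1", 100, "A", c("G", "T"), af = c(0.1, 0.3),
                        calls = list(S1 = sample_call("1/2", 30L,
                                                      pl = c(50, 20, 0, 40, 10, 60))))
  out <- split_multiallelic(rec)
  expect_equal(out[[1]]$calls$S1$pl, c(50, 20, 0) - 0)
  expect_equal(out[[2]]$calls$S1$pl, c(50, 40, 60) - 40)
})

test_that("normalize_variant left-aligns the worked deletion in a T-run", {
  ref_seq <- c(chr1 = "CTTTTC")
  rec <- make_rec(pos = 4, ref = "TT", alt = "T")
  out <- normalize_variant(rec, ref_seq)
  expect_equal(out$pos, 1L)
  expect_equal(out$ref, "CT")
  expect_equal(out$alts, "C")
  # idempotent and edit-equivalent
  again <- normalize_variant(out, ref_seq)
  expect_equal(again[c("pos", "ref", "alts")], out[c("pos", "ref", "alts")])
  expect_equal(apply_edit(ref_seq[[1]], rec$pos, rec$ref, rec$alts),
               apply_edit(ref_seq[[1]], out$pos, out$ref, out$alts))
})

test_that("normalize_variant leaves SNPs unchanged and checks the reference", {
  ref_seq <- c(chr1 = "ACGTACGT")
  snp <- make_rec(pos = 3, ref = "G", alt = "A")
  out <- normalize_variant(snp, ref_seq)
  expect_equal(out[c("pos", "ref", "alts")], snp[c("pos", "ref", "alts")])
  wrong <- make_rec(pos = 3, ref = "T", alt = "A")
  expect_error(normalize_variant(wrong, ref_seq), "disagrees with reference")
})

test_that("normalize_variant without a reference degrades to parsimony trimming", {
  rec <- make_rec(pos = 10, ref = "ATT", alt = "AT")
  expect_warning(out <- normalize_variant(rec, NULL), "left-alignment skipped")
  expect_equal(out$ref, "AT")
  expect_equal(out$alts, "A")
  expect_equal(out$pos, 10L)
})

test_that("ld_prune drops later variants in perfectly correlated pairs", {
  g <- rbind(c(0, 1, 2, 0), c(0, 1, 2, 0))
  expect_equal(ld_prune(g, 0.5, window = 2, step = 1), 1L)
  anti <- rbind(c(0, 0, 1, 1, 2, 2), c(2, 2, 1, 1, 0, 0))
  expect_equal(ld_prune(anti, 0.5, window = 2, step = 1), 1L)
  # monomorphic rows have r^2 defined as 0 and are never pruned for LD
  mono <- rbind(c(0, 1, 2, 0), c(1, 1, 1, 1))
  expect_equal(ld_prune(mono, 0.1, window = 2, step = 1), c(1L, 2L))
})

test_that("ld_prune retention matches a brute-force Pearson oracle", {
  x <- c(0, 1, 2, 0); y <- c(0, 1, 0, 1)
  r2 <- brute_pearson(x, y)^2
  g <- rbind(x, y)
  expect_equal(ld_prune(g, r2 + 1e-9, window = 2, step = 1), c(1L, 2L))
  expect_equal(ld_prune(g, r2 - 1e-9, window = 2, step = 1), 1L)
})

test_that("merge_samples unions sites and makes missingness explicit", {
  a <- list(make_rec(pos = 100, ref = "A", alt = "G", sample = "A"),
            make_rec(pos = 200, ref = "C", alt = "T", sample = "A"))
  b <- list(make_rec(pos = 100, ref = "A", alt = "G", sample = "B"),
            make_rec(pos = 200, ref = "C", alt = "T", sample = "B"))
  ct <- merge_samples(list(A = a, B = b))
  expect_equal(nrow(ct$sites), 2L)
  expect_equal(n_missing_calls(ct), 0L)

  disjoint <- merge_samples(list(
    A = list(make_rec(pos = 100, ref = "A", alt = "G", sample = "A")),
    B = list(make_rec(pos = 200, ref = "C", alt = "T", sample = "B"))))
  expect_equal(dim(disjoint$gt), c(2L, 2L))
  expect_equal(n_missing_calls(disjoint), 2L)

  expect_error(merge_samples(list(A = a, A = b)), "duplicate patient")
})

test_that("merged missing-call count equals sites x patients minus calls", {
  set.seed(2)
  pos_pool <- seq(100, 1000, by = 100)
  tables <- list()
  total_calls <- 0L
  for (p in c("P1", "P2", "P3")) {
    pos <- sort(sample(pos_pool, sample(3:8, 1)))
    total_calls <- total_calls + length(pos)
    tables[[p]] <- lapply(pos, function(x)
      make_rec(pos = x, ref = "A", alt = "G", sample = p))
  }
  ct <- merge_samples(tables)
  expect_equal(n_missing_calls(ct),
               nrow(ct$sites) * 3L - total_calls)
})

test_that("impute_missing fills reference calls of average quality and depth", {
  tables <- list(
    A = list(make_rec(pos = 100, ref = "A", alt = "G", dp = 20L,
                      pl = c(40, 0, 80), sample = "A"),
             make_rec(pos = 200, ref = "C", alt = "T", dp = 30L,
                      pl = c(0, 60, 120), gt = "0/0", sample = "A")),
    B = list(make_rec(pos = 300, ref = "G", alt = "A", dp = 10L,
                      pl = c(0, 50, 100), gt = "0/0", sample = "B"))
  )
  ct <- impute_missing(merge_samples(tables))
  # patient A: called DPs {20,30} -> 25; GQs {40,60} -> g=50 -> PL [0,50,100]
  expect_equal(n_missing_calls(ct), 0L)
  expect_equal(unname(ct$gt["chr1:300:G>A", "A"]), "0/0")
  expect_equal(unname(ct$dp["chr1:300:G>A", "A"]), 25)
  expect_equal(unname(ct$pl["chr1:300:G>A", "A"]), "0,50,100")
  expect_true(ct$imputed["chr1:300:G>A", "A"])
  # originally called entries untouched
  expect_false(any(ct$imputed[c("chr1:100:A>G", "chr1:200:C>T"), "A"]))
  expect_equal(unname(ct$dp["chr1:100:A>G", "A"]), 20)

  # a table with no missing calls passes through unchanged
  full <- merge_samples(list(
    A = list(make_rec(pos = 100, ref = "A", alt = "G", sample = "A"))))
  expect_identical(impute_missing(full), full)
})

test_that("impute_missing refuses a patient with zero called sites", {
  only_missing <- merge_samples(list(
    A = list(make_rec(pos = 100, ref = "A", alt = "G", sample = "A")),
    B = list(variant_record("chr1", 100, "A", "G", 0.2,
                            calls = list(B = sample_call(NA))))))
  expect_error(impute_missing(only_missing), "patient B")
})

test_that("to_patient_matrix transposes and round-trips with the call table", {
  one <- impute_missing(merge_samples(list(
    A = list(make_rec(pos = 100, ref = "A", alt = "G", sample = "A")))))
  pm1 <- to_patient_matrix(one)
  expect_equal(dim(pm1), c(1L, 5L))  # mrn + 4 feature columns

  tables <- list(
    A = list(make_rec(pos = 100, ref = "A", alt = "G", gt = "0/1", sample = "A"),
             make_rec(pos = 200, ref = "C", alt = "T", gt = "1/1", sample = "A")),
    B = list(make_rec(pos = 100, ref = "A", alt = "G", gt = "0/0", sample = "B")),
    C = list(make_rec(pos = 200, ref = "C", alt = "T", gt = "0/1", sample = "C"))
  )
  ct <- impute_missing(merge_samples(tables))
  pm <- to_patient_matrix(ct)
  expect_equal(dim(pm), c(3L, 9L))
  # spot checks against the site-major table
  expect_equal(pm[pm$mrn == "A", "chr1:100:A>G:GT"], 1)
  expect_equal(pm[pm$mrn == "A", "chr1:200:C>T:GT"], 2)
  expect_equal(pm[pm$mrn == "B", "chr1:100:A>G:GT"], 0)
  expect_equal(pm[pm$mrn == "C", "chr1:100:A>G:GT"], 0)  # imputed hom-ref
  expect_equal(unique(pm[["chr1:100:A>G:AF"]]), ct$sites$af[1])

  # transpose twice: shared fields identical (genotypes were unphased)
  back <- matrix_to_call_table(pm)
  expect_equal(back$sites, ct$sites)
  expect_equal(back$gt, ct$gt)
  expect_equal(back$dp, ct$dp)
  expect_equal(back$pl, ct$pl)
  expect_equal(back$imputed, ct$imputed)
  expect_error(to_patient_matrix(merge_samples(list(
    A = list(make_rec(pos = 100, ref = "A", alt = "G", sample = "A")),
    B = list(make_rec(pos = 200, ref = "C", alt = "T", sample = "B"))))),
    "impute_missing")
})

test_that("TSV round trip is exact, including PL strings and imputed flags", {
  tables <- list(
    A = list(make_rec(pos = 100, ref = "A", alt = "G", gt = "0/1", sample = "A")),
    B = list(make_rec(pos = 200, ref = "C", alt = "T", gt = "1/1", sample = "B"))
  )
  pm <- to_patient_matrix(impute_missing(merge_samples(tables)))
  path <- tempfile(fileext = ".tsv")
  write_matrix_tsv(pm, path)
  rt <- read_matrix_tsv(path)
  expect_equal(as.data.frame(rt), as.data.frame(pm))
  expect_equal(attr(rt, "imputed")[rownames(attr(pm, "imputed")),
                                   colnames(attr(pm, "imputed"))],
               attr(pm, "imputed"))

  # empty matrix -> header-only file, readable back
  empty <- structure(data.frame(mrn = character(0), stringsAsFactors = FALSE),
                     class = c("patient_matrix", "data.frame"))
  p2 <- tempfile(fileext = ".tsv")
  write_matrix_tsv(empty, p2)
  expect_length(readLines(p2), 1L)
  expect_equal(nrow(read_matrix_tsv(p2)), 0L)

  # ragged row -> format error naming the line
  p3 <- tempfile(fileext = ".tsv")
  writeLines(c("mrn\tx\ty", "A\t1\t2", "B\t1"), p3)
  expect_error(read_matrix_tsv(p3), "format error.*line 3")
})

test_that("vcf_to_matrix chains the stages and reports pruning", {
  lines_a <- vcf_fixture_lines(
    c("chr1\t100\t.\tA\tG,T\t50\tPASS\tAF=0.2,0.1\tGT:DP:PL\t1/2:30:50,20,0,40,10,60",
      "chr1\t200\t.\tC\tT\t50\tPASS\tAF=0.1\tGT:DP:PL\t0/1:25:30,0,30"),
    sample = "A")
  lines_b <- vcf_fixture_lines(
    "chr1\t200\t.\tC\tT\t50\tPASS\tAF=0.1\tGT:DP:PL\t1/1:20:90,40,0",
    sample = "B")
  dir <- tempfile(); dir.create(dir)
  writeLines(lines_a, file.path(dir, "A.vcf"))
  writeLines(lines_b, file.path(dir, "B.vcf"))
  pm <- vcf_to_matrix(list.files(dir, full.names = TRUE), r2 = NULL)
  expect_setequal(pm$mrn, c("A", "B"))
  # multiallelic site split into two biallelic sites: 3 sites x 4 cols + mrn
  expect_equal(ncol(pm), 13L)
  expect_equal(sum(attr(pm, "imputed")), 2L)  # B imputed at both split sites
})
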