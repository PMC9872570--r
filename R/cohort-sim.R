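#' Default breast-cancer pharmacogenomic simulation module
#'
#' A small state machine in the style of a Synthea disease module: every
#' simulated patient is an adult female (ages 30-90) who develops breast
#' cancer, is assigned one of two anthracyclines (Doxorubicin or
#' Epirubicin, 50/50 branch), and either survives or not. Survival depends
#' on the drug-by-variant interaction: carriers of the pharmacogenomic
#' variant survive with probability 0.9 on Epirubicin, non-carriers with
#' probability 0.9 on Doxorubicin, and every other combination (including
#' untreated) stays at the 0.5 baseline. Carrier prevalence defaults to
#' 0.5, which maximizes the power of the four-group study.
#'
#' Condition and medication codes are synthetic fixture constants, not
#' asserted real SNOMED/RxNorm bindings.
#'
#' @param carrier_prob Probability a patient carries the variant.
#' @param drug_probs Named branch probabilities over the two drugs (must
#'   sum to 1).
#' @param untreated_arm If `TRUE`, a third "none" branch is added and
#'   `drug_probs` renormalized to make room for it.
#' @return A `module_spec` list: `states` (each with a `transitions`
#'   probability table), `survival_table`, `carrier_prob`,
#'   `untreated_survival`, `condition_code`, `pgx_site` and `sim_date`.
#' @export
default_module <- function(carrier_prob = 0.5,
                           drug_probs = c(Doxorubicin = 0.5, Epirubicin = 0.5),
                           untreated_arm = FALSE) {
  if (untreated_arm) {
    drug_probs <- c(drug_probs / sum(drug_probs) * 2 / 3, none = 1 / 3)
  }
  branch <- stats::setNames(as.numeric(drug_probs),
                            paste0("Assign_", names(drug_probs)))
  med_states <- stats::setNames(lapply(names(drug_probs), function(d) {
    list(type = "medication", drug = d, transitions = c(Outcome = 1))
  }), paste0("Assign_", names(drug_probs)))
  spec <- list(
    name = "breast_cancer_pgx",
    states = c(
      list(
        Initial = list(type = "initial", transitions = c(FemaleAdult = 1)),
        FemaleAdult = list(type = "demographics", gender = "female",
                           age_range = c(30L, 90L),
                           transitions = c(BreastCancerOnset = 1)),
        BreastCancerOnset = list(type = "condition",
                                 code = "SYN-BC-001",
                                 display = "Breast cancer (synthetic module)",
                                 transitions = branch)
      ),
      med_states,
      list(
        Outcome = list(type = "outcome", transitions = c(Terminal = 1)),
        Terminal = list(type = "terminal", transitions = NULL)
      )
    ),
    survival_table = data.frame(
      carrier = c(FALSE, TRUE, TRUE, FALSE),
      drug = c("Doxorubicin", "Epirubicin", "Doxorubicin", "Epirubicin"),
      p_survive = c(0.9, 0.9, 0.5, 0.5),
      stringsAsFactors = FALSE
    ),
    untreated_survival = 0.5,
    carrier_prob = carrier_prob,
    sim_date = as.Date("2022-01-01")
  )
  class(spec) <- "module_spec"
  validate_module(spec)
}

#' Validate a simulation module specification
#'
#' Checks that every state's outgoing transition probabilities sum to 1,
#' that all probabilities (transitions, survival, carrier prevalence) lie
#' in `[0, 1]`, and that the survival table covers the drug branches.
#'
#' @param module A `module_spec` (or plain list in the same shape, e.g.
#'   read from a JSON config via [read_module()]).
#' @return The validated module, invisibly classed `module_spec`.
#' @export
validate_module <- function(module) {
  problems <- character(0)
  for (nm in names(module$states)) {
    tr <- module$states[[nm]]$transitions
    if (is.null(tr)) next
    if (any(tr < 0 | tr > 1)) {
      problems <- c(problems, sprintf("state %s: transition probability outside [0,1]", nm))
    }
    if (abs(sum(tr) - 1) > 1e-9) {
      problems <- c(problems, sprintf("state %s: transitions sum to %g, not 1", nm, sum(tr)))
    }
  }
  st <- module$survival_table
  if (is.null(st) || any(st$p_survive < 0 | st$p_survive > 1)) {
    problems <- c(problems, "survival_table probabilities must lie in [0,1]")
  }
  if (module$carrier_prob < 0 || module$carrier_prob > 1) {
    problems <- c(problems, "carrier_prob must lie in [0,1]")
  }
  if (length(problems)) {
    stop("invalid module spec:\n  - ", paste(problems, collapse = "\n  - "))
  }
  class(module) <- "module_spec"
  invisible(module)
}

#' Read a module specification from a JSON config
#'
#' @param path JSON file whose structure mirrors [default_module()] output
#'   (`states`, `survival_table`, `carrier_prob`, ...).
#' @return A validated `module_spec`.
#' @export
read_module <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  base <- default_module()
  for (nm in intersect(names(raw), names(base))) base[[nm]] <- raw[[nm]]
  if (!is.null(raw$states)) {
    base$states <- lapply(raw$states, function(s) {
      s$transitions <- unlist(s$transitions)
      s
    })
  }
  if (!is.null(raw$survival_table)) {
    base$survival_table <- as.data.frame(raw$survival_table,
                                         stringsAsFactors = FALSE)
  }
  base$sim_date <- as.Date(base$sim_date)
  validate_module(base)
}

# the designated pharmacogenomic site (a synthetic fixture constant)
#' @rdname default_module
#' @export
pgx_site <- function() {
  data.frame(chrom = "chr1", pos = 500000L, ref = "A", alt = "G", af = 0.5,
             stringsAsFactors = FALSE)
}

#' Simulate a patient cohort through the module state machine
#'
#' Each patient's randomness comes from an independent stream derived from
#' the single cohort seed and the patient index, so cohort content is
#' reproducible and invariant to generation order. Ages are uniform
#' integers over the module's age range; carrier status, drug branch and
#' survival are drawn per the module's probability tables (a walk of the
#' state machine from `Initial` to `Terminal`).
#'
#' @param n Number of patients (`>= 1`).
#' @param module A `module_spec`; defaults to [default_module()].
#' @param seed Integer seed for the whole cohort.
#' @return A `sim_cohort` data frame: `mrn`, `sex`, `age`, `carrier`,
#'   `gt_pgx` (diploid genotype consistent with carrier status), `drug`,
#'   `survived`.
#' @export
simulate_cohort <- function(n, module = default_module(), seed = 1L) {
  stopifnot(n >= 1)
  module <- validate_module(module)
  demo <- module$states$FemaleAdult
  age <- integer(n); carrier <- logical(n); gt_pgx <- character(n)
  drug <- character(n); survived <- logical(n)
  ages <- demo$age_range[1]:demo$age_range[2]
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, i))
    age[i] <- sample(ages, 1L)
    carrier[i] <- stats::runif(1) < module$carrier_prob
    gt_pgx[i] <- if (carrier[i]) {
      sample(c("0/1", "1/1"), 1L, prob = c(0.8, 0.2))
    } else "0/0"

    state <- "Initial"
    d <- NA_character_
    s <- NA
    while (!identical(state, "Terminal")) {
      node <- module$states[[state]]
      if (identical(node$type, "medication")) d <- node$drug
      if (identical(node$type, "outcome")) {
        s <- stats::runif(1) < survival_prob(module, carrier[i], d)
      }
      tr <- node$transitions
      state <- if (length(tr) == 1L) names(tr) else
        sample(names(tr), 1L, prob = tr)
    }
    drug[i] <- if (identical(d, "none")) NA_character_ else d
    survived[i] <- s
  }
  out <- data.frame(mrn = sprintf("P%05d", seq_len(n)), sex = demo$gender,
                    age = age, carrier = carrier, gt_pgx = gt_pgx,
                    drug = drug, survived = survived,
                    stringsAsFactors = FALSE)
  class(out) <- c("sim_cohort", "data.frame")
  out
}

survival_prob <- function(module, carrier, drug) {
  if (is.na(drug) || identical(drug, "none")) return(module$untreated_survival)
  st <- module$survival_table
  hit <- st$carrier == carrier & st$drug == drug
  if (!any(hit)) return(module$untreated_survival)
  st$p_survive[hit][1]
}

#' Emit a FHIR R4 bundle for one simulated patient
#'
#' The bundle holds a Patient (MR identifier, female, birth date placing
#' the patient at exactly their simulated age on the module's simulation
#' date, `deceasedDateTime` iff they did not survive), a Condition with
#' the module's breast-cancer code (onset at the simulation date) and one
#' MedicationRequest for the assigned drug. Flattening the bundle with
#' [parse_bundle()] + [flatten_to_table()] recovers `mrn`, drug and
#' survival exactly.
#'
#' @param patient One row of a `sim_cohort`.
#' @param module The `module_spec` used to simulate the cohort.
#' @return A single JSON string (the bundle document).
#' @export
emit_fhir <- function(patient, module = default_module()) {
  sim_date <- as.Date(module$sim_date)
  birth <- sprintf("%d-01-01", as.integer(format(sim_date, "%Y")) - patient$age)
  day <- format(sim_date, "%Y-%m-%d")
  pat_res <- list(
    resourceType = "Patient",
    id = paste0("pat-", patient$mrn),
    identifier = list(list(
      type = list(coding = list(list(
        system = "http://terminology.hl7.org/CodeSystem/v2-0203",
        code = "MR"))),
      value = patient$mrn)),
    gender = patient$sex,
    birthDate = birth
  )
  if (!isTRUE(patient$survived)) {
    pat_res$deceasedDateTime <- paste0(day, "T12:00:00Z")
  }
  subject <- list(reference = paste0("urn:uuid:pat-", patient$mrn))
  cond_state <- module$states$BreastCancerOnset
  entries <- list(
    list(fullUrl = paste0("urn:uuid:pat-", patient$mrn), resource = pat_res),
    list(fullUrl = paste0("urn:uuid:cond-", patient$mrn),
         resource = list(
           resourceType = "Condition",
           id = paste0("cond-", patient$mrn),
           subject = subject,
           code = list(coding = list(list(system = "urn:synthetic:condition",
                                          code = cond_state$code,
                                          display = cond_state$display))),
           onsetDateTime = paste0(day, "T00:00:00Z")))
  )
  if (!is.na(patient$drug)) {
    entries[[length(entries) + 1L]] <- list(
      fullUrl = paste0("urn:uuid:med-", patient$mrn),
      resource = list(
        resourceType = "MedicationRequest",
        id = paste0("med-", patient$mrn),
        subject = subject,
        status = "completed", intent = "order",
        medicationCodeableConcept = list(
          text = patient$drug,
          coding = list(list(system = "urn:synthetic:drug",
                             code = toupper(substr(patient$drug, 1L, 4L))))),
        authoredOn = paste0(day, "T00:00:00Z")))
  }
  bundle <- list(resourceType = "Bundle", type = "collection", entry = entries)
  as.character(jsonlite::toJSON(bundle, auto_unbox = TRUE))
}

#' Generate a sorted panel of background variant sites
#'
#' Biallelic SNP sites on one contig with allele frequencies drawn
#' uniformly on `[0.05, 0.5]`; positions avoid the pharmacogenomic site.
#' Used as the non-causal background in emitted VCFs so that merging,
#' LD pruning and imputation have realistic material to work on.
#'
#' @param n_sites Number of background sites.
#' @param seed Integer seed.
#' @return Data frame `chrom`, `pos`, `ref`, `alt`, `af`, sorted by
#'   position.
#' @export
default_background_sites <- function(n_sites = 50L, seed = 1L) {
  set.seed(derive_seed(seed, 0L))
  pos <- sort(sample(setdiff(seq(10000L, 2000000L, by = 100L), pgx_site()$pos),
                     n_sites))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1),
                USE.NAMES = FALSE)
  data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
             af = round(stats::runif(n_sites, 0.05, 0.5), 4),
             stringsAsFactors = FALSE)
}

#' Emit a per-patient VCF document
#'
#' Writes a valid VCF 4.2 document (as a character vector of lines) for
#' one patient: the pharmacogenomic site carries the patient's simulated
#' genotype, background sites draw genotypes from Hardy-Weinberg
#' proportions at their allele frequencies, and each background call is
#' independently made missing (`./.:.:.`) with probability
#' `missing_rate` to exercise downstream imputation. The
#' pharmacogenomic site itself is never dropped, since it encodes the
#' carrier status the study needs. Depth is Poisson(30); PLs are a
#' consistent triple anchored at zero for the called genotype.
#'
#' @param patient One row of a `sim_cohort`.
#' @param background_sites Site panel as from [default_background_sites()].
#' @param missing_rate Per-call drop probability in `[0, 1]`.
#' @param seed Integer seed (the patient's MRN index is mixed in by the
#'   caller via [derive_seed()] when emitting whole cohorts).
#' @return Character vector of VCF lines; `write_vcf_lines()` writes them.
#' @export
emit_vcf <- function(patient, background_sites = default_background_sites(),
                     missing_rate = 0.1, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate <= 1)
  set.seed(seed)
  pgx <- pgx_site()
  sites <- rbind(background_sites,
                 cbind(pgx, stringsAsFactors = FALSE))
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  is_pgx <- sites$pos == pgx$pos & sites$chrom == pgx$chrom

  n <- nrow(sites)
  gts <- character(n)
  for (i in seq_len(n)) {
    if (is_pgx[i]) {
      gts[i] <- patient$gt_pgx
    } else {
      p <- sites$af[i]
      gts[i] <- sample(c("0/0", "0/1", "1/1"), 1L,
                       prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
    }
  }
  dp <- pmax(1L, stats::rpois(n, 30))
  gq <- sample(30:80, n, replace = TRUE)
  fmt <- vapply(seq_len(n), function(i) {
    pl <- switch(gts[i],
                 "0/0" = c(0, gq[i], 2 * gq[i]),
                 "0/1" = c(gq[i], 0, gq[i] + sample(10:40, 1L)),
                 "1/1" = c(2 * gq[i], gq[i], 0))
    sprintf("%s:%d:%s", gts[i], dp[i], paste(pl, collapse = ","))
  }, character(1))
  drop <- stats::runif(n) < missing_rate & !is_pgx
  fmt[drop] <- "./.:.:."

  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(sites$chrom)),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled Genotype Likelihoods\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", patient$mrn), collapse = "\t"),
    sprintf("%s\t%d\t.\t%s\t%s\t50\tPASS\tAF=%s\tGT:DP:PL\t%s",
            sites$chrom, sites$pos, sites$ref, sites$alt,
            format(sites$af, trim = TRUE, scientific = FALSE), fmt))
}

#' @param lines Character vector from [emit_vcf()].
#' @param path Output file path.
#' @rdname emit_vcf
#' @export
write_vcf_lines <- function(lines, path) {
  writeLines(lines, path)
  invisible(path)
}

#' Labeled Gaussian-mixture feature generator
#'
#' Draws `n` points from `k` spherical Gaussian components. Centers sit at
#' the origin for `k = 1` and otherwise equally spaced on a circle in the
#' first two feature dimensions with adjacent centers `separation` apart,
#' so no three centers are collinear and each component is a genuinely
#' distinct mode. Used as ground-truthed material for clustering tests
#' (recovery, elbow selection, validity indices).
#'
#' @param n Total points.
#' @param k Number of components (`>= 1`).
#' @param separation Center-to-center spacing (`> 0`).
#' @param sigma Within-component standard deviation.
#' @param dim Feature dimension (default 2).
#' @param seed Integer seed.
#' @return List with `X` (n-by-dim matrix) and `labels` (integer true
#'   component per row).
#' @export
gaussian_mixture_features <- function(n, k, separation = 5, sigma = 1,
                                      dim = 2L, seed = 1L) {
  stopifnot(k >= 1L, separation > 0, n >= k)
  set.seed(seed)
  labels <- sort(rep_len(seq_len(k), n))
  centers <- matrix(0, k, dim)
  if (k >= 2L) {
    stopifnot(dim >= 2L)
    radius <- separation / (2 * sin(pi / k))
    theta <- 2 * pi * (seq_len(k) - 1L) / k
    centers[, 1] <- radius * cos(theta)
    centers[, 2] <- radius * sin(theta)
  }
  X <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * dim, sd = sigma), n, dim)
  list(X = X, labels = labels)
}

#' Write a full synthetic cohort to disk
#'
#' Convenience wrapper used by the pipeline: simulates a cohort and writes
#' `fhir/<mrn>.json`, `vcf/<mrn>.vcf` and a `truth.tsv` with the
#' simulator's ground truth.
#'
#' @param n Cohort size.
#' @param out_dir Output directory (created if needed).
#' @param module A `module_spec`.
#' @param background_sites Background site panel.
#' @param missing_rate Per-call VCF drop probability.
#' @param seed Integer cohort seed.
#' @return The `sim_cohort` data frame, invisibly; files on disk.
#' @export
write_cohort <- function(n, out_dir, module = default_module(),
                         background_sites = default_background_sites(),
                         missing_rate = 0.1, seed = 1L) {
  cohort <- simulate_cohort(n, module, seed)
  fhir_dir <- file.path(out_dir, "fhir")
  vcf_dir <- file.path(out_dir, "vcf")
  dir.create(fhir_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(vcf_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort))) {
    p <- cohort[i, ]
    writeLines(emit_fhir(p, module), file.path(fhir_dir, paste0(p$mrn, ".json")))
    write_vcf_lines(
      emit_vcf(p, background_sites, missing_rate,
               seed = derive_seed(seed, 100000L + i)),
      file.path(vcf_dir, paste0(p$mrn, ".vcf")))
  }
  utils::write.table(cohort, file.path(out_dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(cohort)
}
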