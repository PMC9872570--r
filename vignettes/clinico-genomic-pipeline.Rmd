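---
title: "Merging FHIR clinical records with long-read variant matrices"
author: "fhirvariant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging FHIR clinical records with long-read variant matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhirvariant)
```

`fhirvariant` turns two awkward inputs — per-patient VCF variant calls and
hierarchical FHIR R4 JSON bundles — into one patient-per-row table, and
runs exploratory clustering and a pharmacogenomic proportion test on it.
This vignette explains the methods, the assumptions behind each stage, the
parameters that matter, and what the built-in simulator does and does not
emulate.

## The genomic matrix

### Normalization and multi-allelic splitting

A fixed-width patient × variant table needs a constant number of columns
per site, so multi-allelic VCF records are split into one biallelic record
per alternate allele. Genotype allele indexes pointing at the focal alt
become 1; indexes pointing at *other* alts become 0. That recode is lossy
(the non-focal alt allele is indistinguishable from reference in the
focal record) and the affected records are flagged; the compensation is
that each record's GT column is a clean dosage of its own alt, and every
site contributes exactly four columns. Phred likelihood vectors are subset
to the three genotypes over {ref, focal alt} and re-anchored at zero; a PL
vector whose length is inconsistent with the allele count is treated as
missing rather than guessed at.

The same variant can be written at many positions in a repeat tract, so
records are reduced to their parsimonious, leftmost representation:
shared trailing bases are truncated; when an allele empties, the preceding
reference base is prepended and the position decremented; finally shared
leading bases are trimmed while both alleles keep length ≥ 2. Two
properties are enforced by tests: the output edit applied to the reference
produces the same sequence as the input edit, and the procedure is a
fixed point of itself (idempotence). Two boundary decisions:

- *No reference available*: left-shifting is impossible without the
  flanking sequence, so normalization degrades to parsimony trimming with
  a warning. The pipeline's own simulated VCFs are emitted already
  left-aligned (SNPs), so this path only matters for external inputs.
- *Contig start*: if an allele empties at position 1 there is no
  preceding base to anchor on. The record is anchored on the base
  *following* the allele instead — the conventional behavior of variant
  normalizers at the sequence boundary — and shifting stops there.

### LD pruning

Nearby variants are inherited together, so their dosage columns are
highly collinear; pruning keeps a mostly-independent panel. We use the
classic sliding-window procedure on dosage-coded genotypes (0/1/2, phase
ignored — the simplest covariance-faithful encoding): within each window
of `window = 50` consecutive variants, advancing by `step = 5`, any pair
of retained variants with squared Pearson correlation ≥ `r2 = 0.5` loses
its *later* member (position order), which makes the output deterministic.
These defaults are the conventional pairwise-pruning settings; all three
are arguments of `ld_prune()` and pipeline config keys. Monomorphic
variants have undefined correlation; their r² is defined as 0 and they
are never pruned for LD. "Within every window" means the windows the
algorithm visits, and the test suite brute-forces exactly those windows.

The end-to-end pipeline exempts the designated pharmacogenomic site from
pruning: a targeted study column must not silently vanish because a
background variant happened to correlate with it.

### Imputation of missing reference calls

Plain VCFs record only confidently called variants, so after merging,
"patient P has no row at site s" usually means "P matched the reference
at s", not "unknown". Each missing call is therefore imputed as a
homozygous-reference call of that patient's average quality and depth:

- `GT = 0/0`,
- `DP = round(mean DP over the patient's called sites)`,
- `PL = [0, g, 2g]` with `g = round(mean genotype quality)`, genotype
  quality being the second-smallest PL entry of a called site.

The `[0, g, 2g]` shape places the reference genotype at likelihood rank
zero and spaces the heterozygote and homozygous-alt genotypes linearly —
"average quality" operationalized as the patient's mean GQ. Both choices
are documented and overridable upstream (the imputation consumes whatever
PLs the merge produced). Every imputed cell is flagged, the flags survive
the TSV round trip in companion `:IMPUTED` columns, and a patient with
*zero* called sites is an error, not a guess. Note the imputed DP is the
*rounded* per-patient mean, so it equals the mean exactly whenever the
mean is an integer.

## The clinical table

Bundles are flattened into one row per MRN (the Patient identifier with
type coding `MR`, falling back to the resource id, since generated bundles
vary). Four resource types are consumed — Patient, Condition,
MedicationRequest, Observation — and others are counted and skipped;
those four are what the downstream analyses use. Repeated resources
become indexed columns (`medication_1..m`) rather than one boolean column
per code: with a desk-scale cohort, indexed columns bound column growth
and keep the table readable. Resource content that does not map to a flat
column is serialized verbatim into a companion `_json` column, so no
value is silently dropped — a property the tests verify by walking the
fixture JSON leaves. Survival is `FALSE` iff `deceasedDateTime` or
`deceasedBoolean = TRUE` is present. Ages are computed in whole calendar
years at a reference date, defaulting to the latest event date in the
cohort (calendar arithmetic, not division by 365.25, which is off by one
across enough leap days).

## The cohort simulator

`default_module()` is a small state machine in the style of a disease
module: Initial → demographic filter (female, ages 30–90, uniform) →
breast-cancer onset → medication branch → outcome → terminal. Outgoing
transition probabilities must sum to one per state; `validate_module()`
enforces that plus range checks. The clinically meaningful content is the
survival table:

| carrier | drug        | P(survive) |
|---------|-------------|-----------|
| no      | Doxorubicin | 0.9       |
| yes     | Epirubicin  | 0.9       |
| yes     | Doxorubicin | 0.5       |
| no      | Epirubicin  | 0.5       |

with 0.5 also the untreated baseline. The carrier prevalence (0.5) and
the drug branch (0.5/0.5) are balanced defaults chosen to maximize the
power of the four-group study, and are configurable; an optional
untreated arm can be added. Condition and drug codes are synthetic
placeholder constants, not asserted real SNOMED/RxNorm bindings. Birth
dates are placed at January 1 of (simulation year − age) against a fixed
simulation date (2022-01-01), so ages round-trip exactly through the FHIR
layer.

Each patient's randomness comes from an independent stream derived from
the cohort seed and the patient index, so cohorts are reproducible and
the first *k* patients of a run are invariant to the total cohort size.

`emit_vcf()` writes the pharmacogenomic genotype (carrier ⇒ at least one
alt allele; het:hom 0.8:0.2) plus background SNPs drawn from
Hardy–Weinberg proportions at per-site allele frequencies uniform on
[0.05, 0.5], depth Poisson(30), and consistent min-zero PL triples. Each
background call is independently dropped with `missing_rate` to exercise
imputation; the pharmacogenomic site itself is never dropped, because it
carries the carrier status the study is about.

What the simulator does *not* emulate: linkage disequilibrium between
background sites (sites are independent, so pruning removes little on
simulated data), sequencing-error-driven genotype noise, longitudinal
encounters, care plans or realistic terminology bindings, and any
correlation between demographics and outcome. Passing tests on simulated
cohorts therefore demonstrate the pipeline's bookkeeping and the
statistics' calibration — not robustness to the messiness of real
clinical archives.

`gaussian_mixture_features()` provides ground-truthed clustering material:
`k` spherical Gaussian components with centers equally spaced on a circle
(adjacent spacing = `separation`), so no three centers are collinear and
each component is a distinct mode. Collinear equally-spaced centers would
make the elbow criterion genuinely ambiguous between *k−1* and *k*.

## Clustering and validity

Inertia here is the **mean** squared distance from each point to its
assigned centroid. The more common convention is the sum; the two differ
by the factor *n* only, so cluster assignments, restart selection and the
elbow position are identical under either — the mean is simply the scale
reported throughout.

`kmeanspp()` implements k-means++ seeding (first center uniform, later
centers with probability proportional to squared distance to the nearest
chosen center) followed by Lloyd iterations until the largest centroid
shift drops below `tol = 1e-6` or `max_iter = 100`, keeping the best of
`n_init = 10` restarts by inertia. An emptied cluster seizes the point
farthest from its current centroid. `dbscan_cluster()` is the standard
density-reachability expansion with noise labeled −1; core/border
assignment is deterministic in input order. `spectral_cluster()` builds
the RBF affinity `exp(−γ‖xᵢ−xⱼ‖²)` (γ = 1 on standardized features),
eigendecomposes the symmetrically normalized affinity, row-normalizes the
top-*k* eigenvector matrix and hands the embedding to `kmeanspp()`.

The cluster count is selected where the inertia curve bends toward the
horizontal, formalized as the *k* maximizing the discrete second
difference `inertia(k−1) − 2·inertia(k) + inertia(k+1)` — the simplest
reproducible reading of an elbow. A curve with no pronounced bend (all
second differences ≈ 0) still returns a selection, with a warning.

Three label-free indices score a clustering: Davies–Bouldin
`(1/k)Σᵢ maxⱼ≠ᵢ (Sᵢ+Sⱼ)/Mᵢⱼ` (lower is better), Calinski–Harabasz
`[BSS/(k−1)]/[WSS/(n−k)]`, and the mean silhouette `(b−a)/max(a,b)`
(singletons score 0). All use Euclidean distance. Degenerate cases are
explicit: coincident centroids make a Davies–Bouldin pair undefined
(error); zero within-cluster scatter makes Calinski–Harabasz infinite
(flagged). DBSCAN noise points are excluded from the indices — which are
undefined for them — and the noise fraction is reported alongside
(`cluster_metrics()`). Every index is verified against an independent
brute-force implementation of its formula to 1e-9 on random instances,
and against hand-computed values on the 1-D fixture {0,2} | {10,12}
(DB = 0.2, CH = 50, silhouette ≈ 0.798).

## The pharmacogenomic study

Each carrier × drug cell is tested one-sided against the untreated
baseline with the one-sample proportion z-test,
`z = (p̂ − p₀)/√(p₀(1−p₀)/n)`, upper-tail normal p-value, no continuity
correction, p₀ = 0.5, α = 0.01. The four cells are treated as four
independent tests with no multiple-testing correction — the study asks
four separate "better than untreated?" questions, not a family-wise one.
When `n·p₀ < 5` the normal approximation is flagged but the result still
returned; empty cells are reported untestable rather than dropped.
Carrier status is derived from the pharmacogenomic genotype column
(dosage ≥ 1), not from any clinical field, so the genomic table remains
the causal source for the exposure.

Calibration is checked empirically: across replicated simulated cohorts
the matched-cell rejection rate rises toward 1 with n while the
mismatched-cell rate stays near α (the suite checks this trend at n = 60
and n = 400 with 40 replicates — sizes chosen to give a clear trend at
desk-scale runtime).

## Numerical and design notes

- Coordinates are 1-based inclusive throughout, matching VCF.
- Site keys are `chrom:pos:ref>alt`; feature columns append `:GT`, `:AF`,
  `:DP`, `:PL`.
- Allele frequency comes from the INFO `AF` field; a site with no AF
  anywhere is assigned the cohort alternate-allele frequency after the
  merge (logged).
- Genotypes are handled unphased; the matrix stores dosage, so the
  patient-matrix round trip is lossless up to phase and the imputed flag.
- Feature encoding: genotypes → dosage, categoricals → one-hot, numerics
  → z-scores; constant columns are dropped (logged) since they carry no
  clustering information.
- The elbow, LD and simulator seeds all flow from a single configured
  seed; `validate_config()` materializes every default so a manifest
  records the complete parameterization. Re-running a config reproduces
  byte-identical artifacts.
- Problem sizes used by the test suite (200-patient full-cycle cohorts,
  10 000-patient calibration cohorts, 1000 random indels, 200 random
  index instances, 100 random 20-variant LD panels) were chosen as
  desk-scale sizes that exercise every code path while keeping the suite
  comfortably interactive.

## Known limitations

- The multi-allelic genotype recode is lossy by design (flagged, logged).
- Imputation assumes missingness means "reference call"; that is the
  right reading for variant-only VCFs but wrong for dropped-out regions —
  inputs with genuinely unsequenced regions need GVCF-style evidence the
  pipeline does not consume.
- FHIR coverage is the four resource types the analyses use; XML/RDF
  encodings, servers and bulk export are out of scope.
- The clustering feature set on real data is a modeling choice the user
  must make (`encode_features()` config); the default picks genotype
  dosages, gender, first medication and age when present.
- Validity-index comparisons across methods are data-dependent; the
  package reports the indices and leaves the judgment to the analyst.
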