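Package: fhirvariant
Title: Merging FHIR Clinical Records with Long-Read Variant Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A local pipeline for combining clinical records stored as FHIR
    R4 JSON bundles with patient genotypes derived from long-read variant
    calls (VCF 4.2). VCFs are normalized (multi-allelic splitting, indel
    left-alignment), pruned for linkage disequilibrium, merged across
    patients, imputed at uncalled sites, and transposed into a patient by
    variant-feature matrix; FHIR bundles are flattened into a one-row-per-
    patient table keyed by medical record number. The merged table feeds
    three analyses: columnar export, patient clustering (k-means++, DBSCAN,
    spectral) with internal validity indices (Davies-Bouldin,
    Calinski-Harabasz, silhouette) and elbow selection, and a one-sided
    proportion z-test pharmacogenomic study. A built-in state-machine
    cohort simulator emits paired synthetic FHIR bundles and VCFs for a
    breast-cancer drug-by-variant survival scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    vcfR,
    arrow,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    Biostrings
Config/testthat/edition: 3
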