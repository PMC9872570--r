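#' Validate a pipeline configuration
#'
#' Fills defaults, rejects unknown keys and reports every violation at
#' once in a single human-readable error. All seeds are explicit after
#' resolution (defaults are materialized into the returned object).
#'
#' @param document Path to a YAML or JSON config file, or a named list.
#' @return A validated `pipeline_config` list.
#' @export
validate_config <- function(document = list()) {
  if (is.character(document) && length(document) == 1L) {
    if (!file.exists(document)) stop("config file not found: ", document)
    document <- if (grepl("\\.json$", document)) {
      jsonlite::fromJSON(document, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(document)
    }
  }
  stopifnot(is.list(document))
  defaults <- list(
    n_patients = 100L, seed = 1L, out_dir = "pipeline_out",
    missing_rate = 0.1, background_sites = 50L,
    ld = list(r2 = 0.5, window = 50L, step = 5L),
    k_range = 1:8, alpha = 0.01,
    pgx_column = paste0(pgx_site()$chrom, ":", pgx_site()$pos, ":",
                        pgx_site()$ref, ">", pgx_site()$alt, ":GT"),
    export_format = "parquet",
    stages = list(simulate = TRUE, variant_matrix = TRUE, clinical = TRUE,
                  merge = TRUE, cluster = TRUE, pgx = TRUE, export = TRUE)
  )
  problems <- character(0)
  unknown <- setdiff(names(document), names(defaults))
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown config key(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, document[setdiff(names(document), unknown)])
  if (!is.numeric(cfg$n_patients) || cfg$n_patients < 1) {
    problems <- c(problems, "n_patients: must be a positive patient count")
  }
  if (!is.numeric(cfg$missing_rate) || cfg$missing_rate < 0 || cfg$missing_rate > 1) {
    problems <- c(problems, "missing_rate: must lie in [0,1]")
  }
  if (!is.null(cfg$ld$r2) && (cfg$ld$r2 < 0 || cfg$ld$r2 > 1)) {
    problems <- c(problems, "ld$r2: squared correlation threshold must lie in [0,1]")
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    problems <- c(problems, "alpha: must lie in (0,1)")
  }
  if (length(cfg$k_range) >= 1 && any(cfg$k_range < 1)) {
    problems <- c(problems, "k_range: cluster counts must be >= 1")
  }
  if (!is.character(cfg$export_format) ||
      !cfg$export_format %in% c("parquet", "csv")) {
    problems <- c(problems, "export_format: must be 'parquet' or 'csv'")
  }
  if (length(problems)) {
    stop("invalid pipeline config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  cfg$n_patients <- as.integer(cfg$n_patients)
  cfg$seed <- as.integer(cfg$seed)
  vlog("config resolved: seed=%d n=%d", cfg$seed, cfg$n_patients)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full local pipeline
#'
#' Executes the enabled stages in dependency order — simulate, VCF to
#' genomic matrix, FHIR to clinical table, merge, clustering, the
#' pharmacogenomic study, columnar export — writing every artifact under
#' `config$out_dir` and recording a run manifest (parameters, seeds,
#' input digests and per-stage row/column counts) to `manifest.json`.
#' Re-running an identical config reproduces identical outputs for the
#' deterministic stages. Any stage error aborts the run naming the stage;
#' the manifest of the stages already completed is preserved on disk.
#'
#' @param config A `pipeline_config` from [validate_config()] (or
#'   anything it accepts).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = validate_config()) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), stages = list(),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  save_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                         digits = NA)
  }
  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) return(invisible(NULL))
    info <- tryCatch(fun(), error = function(e) {
      save_manifest()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- info
    save_manifest()
  }

  module <- default_module()
  sites <- default_background_sites(config$background_sites, config$seed)
  cohort <- NULL; pm <- NULL; clinical <- NULL; merged <- NULL

  run_stage("simulate", function() {
    cohort <<- write_cohort(config$n_patients, out_dir, module, sites,
                            config$missing_rate, config$seed)
    list(seed = config$seed, n = nrow(cohort),
         truth_digest = unname(tools::md5sum(file.path(out_dir, "truth.tsv"))))
  })
  run_stage("variant_matrix", function() {
    vcfs <- sort(list.files(file.path(out_dir, "vcf"), "\\.vcf$",
                            full.names = TRUE))
    if (!length(vcfs)) stop("no VCF inputs found under ", out_dir, "/vcf")
    pm <<- vcf_to_matrix(vcfs, r2 = config$ld$r2, window = config$ld$window,
                         step = config$ld$step, keep_sites = pgx_site())
    write_matrix_tsv(pm, file.path(out_dir, "matrix.tsv"))
    list(patients = nrow(pm), features = ncol(pm) - 1L,
         sites_pruned = attr(pm, "n_pruned"),
         inputs_digest = unname(tools::md5sum(vcfs[1])))
  })
  run_stage("clinical", function() {
    bundles <- sort(list.files(file.path(out_dir, "fhir"), "\\.json$",
                               full.names = TRUE))
    if (!length(bundles)) stop("no FHIR bundles found under ", out_dir, "/fhir")
    resources <- unlist(lapply(bundles, parse_bundle), recursive = FALSE)
    clinical <<- flatten_to_table(resources)
    path <- file.path(out_dir, paste0("clinical.", config$export_format))
    write_columnar(clinical, path)
    list(patients = nrow(clinical), columns = ncol(clinical))
  })
  run_stage("merge", function() {
    merged <<- merge_tables(clinical, pm)
    drop <- attr(merged, "drop_report")
    write_columnar(merged, file.path(out_dir,
                                     paste0("merged.", config$export_format)))
    list(rows = nrow(merged), columns = ncol(merged),
         dropped_clinical_only = length(drop$clinical_only),
         dropped_genomic_only = length(drop$genomic_only))
  })
  run_stage("cluster", function() {
    X <- encode_features(merged)
    elbow <- elbow_select(X, config$k_range, seed = config$seed)
    km <- kmeanspp(X, elbow$k, seed = config$seed)
    metrics <- cluster_metrics(X, km)
    utils::write.table(
      data.frame(k = elbow$k_range, inertia = elbow$inertia),
      file.path(out_dir, "inertia_curve.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(selected_k = elbow$k, inertia = km$inertia,
         davies_bouldin = metrics$davies_bouldin,
         calinski_harabasz = metrics$calinski_harabasz,
         silhouette = metrics$silhouette)
  })
  run_stage("pgx", function() {
    study <- pgx_study(merged, config$pgx_column, alpha = config$alpha)
    utils::write.table(study$results, file.path(out_dir, "pgx_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res <- study$results[study$results$testable, ]
    list(cells = nrow(study$results),
         significant = res$drug[res$significant],
         p_values = stats::setNames(
           res$p, paste0(ifelse(res$carrier, "carrier", "noncarrier"),
                         "_", res$drug)))
  })
  run_stage("export", function() {
    # Application 1: columnar export of both tables plus the merged view
    path <- file.path(out_dir, paste0("export_genomic.", config$export_format))
    write_columnar(pm, path)
    list(files = basename(c(path,
                            file.path(out_dir,
                                      paste0("clinical.", config$export_format)),
                            file.path(out_dir,
                                      paste0("merged.", config$export_format)))))
  })
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  save_manifest()
  invisible(manifest)
}
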