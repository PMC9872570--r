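#' FHIR R4 bundle parsing and flattening
#'
#' Clinical data arrives as FHIR R4 JSON bundles, one per patient in the
#' Synthea layout. [parse_bundle()] extracts the supported resources
#' (Patient, Condition, MedicationRequest, Observation), resolving each
#' non-Patient resource's subject reference to the bundle Patient's
#' medical record number (MRN); [flatten_to_table()] turns the resources
#' of a whole cohort into a one-row-per-patient table keyed by MRN.
#'
#' MRN is the Patient identifier whose type coding is `"MR"`; when absent
#' the Patient `id` is used as a fallback (logged), since Synthea bundles
#' vary. Subject references of the forms `"Patient/<id>"` and
#' `"urn:uuid:<id>"` are both resolved. Unsupported resource types are
#' skipped and counted (attribute `skipped`).
#'
#' @param doc A bundle: file path, JSON string, or already-parsed list.
#' @return `parse_bundle`: list of `fhir_resource` objects (`resource_type`,
#'   `raw`, `subject_mrn`), with attribute `skipped` (named counts of
#'   skipped resource types).
#' @export
parse_bundle <- function(doc) {
  if (is.character(doc) && length(doc) == 1L && file.exists(doc)) {
    doc <- paste(readLines(doc, warn = FALSE), collapse = "\n")
  }
  b <- if (is.list(doc)) doc else jsonlite::fromJSON(doc, simplifyVector = FALSE)
  if (!identical(b$resourceType, "Bundle") || is.null(b$entry)) {
    stop("document is not a FHIR Bundle with an entry array")
  }
  supported <- c("Patient", "Condition", "MedicationRequest", "Observation")
  entries <- b$entry

  # first pass: index Patients by resource id and fullUrl
  id_map <- list()
  for (i in seq_along(entries)) {
    res <- entries[[i]]$resource
    rt <- res$resourceType
    if (is.null(rt)) stop("parse error: bundle entry ", i, " missing resourceType")
    if (identical(rt, "Patient")) {
      mrn <- patient_mrn(res)
      if (!is.null(res$id)) id_map[[paste0("Patient/", res$id)]] <- mrn
      fu <- entries[[i]]$fullUrl
      if (!is.null(fu)) id_map[[fu]] <- mrn
    }
  }

  out <- list()
  skipped <- integer(0)
  for (i in seq_along(entries)) {
    res <- entries[[i]]$resource
    rt <- res$resourceType
    if (!rt %in% supported) {
      skipped[rt] <- (if (rt %in% names(skipped)) skipped[[rt]] else 0L) + 1L
      vlog("skipping unsupported resource type %s (entry %d)", rt, i)
      next
    }
    if (identical(rt, "Patient")) {
      mrn <- patient_mrn(res)
    } else {
      ref <- res$subject$reference
      mrn <- if (!is.null(ref) && !is.null(id_map[[ref]])) id_map[[ref]] else NULL
      if (is.null(mrn)) {
        stop("orphan resource: entry ", i, " (", rt,
             ") has no resolvable subject reference")
      }
    }
    out[[length(out) + 1L]] <- structure(
      list(resource_type = rt, raw = res, subject_mrn = mrn),
      class = "fhir_resource"
    )
  }
  attr(out, "skipped") <- skipped
  out
}

patient_mrn <- function(res) {
  for (id in res$identifier) {
    for (cd in id$type$coding) {
      if (identical(cd$code, "MR") && !is.null(id$value)) return(id$value)
    }
  }
  if (!is.null(res$id)) {
    vlog("Patient has no MR identifier; falling back to resource id %s", res$id)
    return(as.character(res$id))
  }
  stop("Patient resource has neither an MR identifier nor an id")
}

# primary code of a CodeableConcept: first coding's code, else text
primary_code <- function(cc) {
  if (is.null(cc)) return(NA_character_)
  if (length(cc$coding) && !is.null(cc$coding[[1]]$code)) {
    return(as.character(cc$coding[[1]]$code))
  }
  if (!is.null(cc$text)) return(as.character(cc$text))
  NA_character_
}

# serialize the parts of a resource not mapped to flat columns; NA when
# nothing is left over
leftover_json <- function(res, mapped) {
  rest <- res[setdiff(names(res), c(mapped, "resourceType", "id", "subject",
                                    "meta"))]
  if (!length(rest)) return(NA_character_)
  as.character(jsonlite::toJSON(rest, auto_unbox = TRUE))
}

#' Build one clinical-table row from a patient's resources
#'
#' Demographics come from the single Patient resource (gender, birth
#' date, age at `reference_date`, survival flag — false iff
#' `deceasedDateTime` or `deceasedBoolean = TRUE` is present). Each
#' Condition contributes its primary code and onset, each
#' MedicationRequest its text and primary code (in onset/authored-date
#' then code order), and each Observation a code/value pair. Resource
#' content not mapped to a flat column is preserved verbatim in a
#' companion `_json` column so no value is silently dropped.
#'
#' @param resources List of `fhir_resource` objects sharing one MRN.
#' @param reference_date `Date` at which age is computed.
#' @return A one-row data frame.
#' @export
extract_patient_row <- function(resources, reference_date = NULL) {
  types <- vapply(resources, `[[`, character(1), "resource_type")
  pats <- resources[types == "Patient"]
  if (length(pats) != 1L) {
    stop("expected exactly one Patient resource, found ", length(pats))
  }
  p <- pats[[1]]$raw
  mrn <- pats[[1]]$subject_mrn
  deceased_dt <- p$deceasedDateTime
  deceased <- !is.null(deceased_dt) || isTRUE(p$deceasedBoolean)
  bd <- if (!is.null(p$birthDate)) as.Date(p$birthDate) else as.Date(NA)
  age <- if (!is.na(bd) && !is.null(reference_date)) {
    ref <- as.Date(reference_date)
    as.numeric(format(ref, "%Y")) - as.numeric(format(bd, "%Y")) -
      (format(ref, "%m%d") < format(bd, "%m%d"))
  } else NA_real_
  row <- data.frame(
    mrn = mrn,
    gender = p$gender %||% NA_character_,
    birth_date = as.character(bd),
    age = age,
    survived = !deceased,
    deceased_date = as.character(deceased_dt %||% NA_character_),
    patient_json = leftover_json(p, c("identifier", "gender", "birthDate",
                                      "deceasedDateTime", "deceasedBoolean")),
    stringsAsFactors = FALSE
  )

  conds <- resources[types == "Condition"]
  if (length(conds)) {
    onset <- vapply(conds, function(r) r$raw$onsetDateTime %||% "", character(1))
    code <- vapply(conds, function(r) primary_code(r$raw$code), character(1))
    ord <- order(onset, code)
    for (j in seq_along(ord)) {
      r <- conds[[ord[j]]]$raw
      row[[sprintf("condition_%d", j)]] <- code[ord[j]]
      row[[sprintf("condition_%d_onset", j)]] <- r$onsetDateTime %||% NA_character_
      row[[sprintf("condition_%d_json", j)]] <-
        leftover_json(r, c("code", "onsetDateTime"))
    }
  }

  meds <- resources[types == "MedicationRequest"]
  if (length(meds)) {
    authored <- vapply(meds, function(r) r$raw$authoredOn %||% "", character(1))
    text <- vapply(meds, function(r) {
      cc <- r$raw$medicationCodeableConcept
      as.character(cc$text %||% primary_code(cc))
    }, character(1))
    ord <- order(authored, text)
    for (j in seq_along(ord)) {
      r <- meds[[ord[j]]]$raw
      row[[sprintf("medication_%d", j)]] <- text[ord[j]]
      row[[sprintf("medication_%d_code", j)]] <-
        primary_code(r$medicationCodeableConcept)
      row[[sprintf("medication_%d_json", j)]] <-
        leftover_json(r, c("medicationCodeableConcept", "authoredOn"))
    }
  }

  obs <- resources[types == "Observation"]
  if (length(obs)) {
    codes <- vapply(obs, function(r) primary_code(r$raw$code), character(1))
    ord <- order(codes)
    seen <- character(0)
    for (j in ord) {
      r <- obs[[j]]$raw
      base <- paste0("observation_", codes[j])
      nm <- base
      k <- 1L
      while (nm %in% seen) { k <- k + 1L; nm <- sprintf("%s_%d", base, k) }
      seen <- c(seen, nm)
      val <- r$valueQuantity$value %||% r$valueString %||%
        r$valueCodeableConcept$text %||% r$valueBoolean %||% NA
      row[[nm]] <- val
      row[[paste0(nm, "_json")]] <-
        leftover_json(r, c("code", "valueQuantity", "valueString",
                           "valueCodeableConcept", "valueBoolean",
                           "effectiveDateTime"))
      if (!is.null(r$effectiveDateTime)) {
        row[[paste0(nm, "_date")]] <- r$effectiveDateTime
      }
    }
  }
  row
}

#' Flatten a cohort's FHIR resources into one table
#'
#' One row per distinct MRN; the column set is the union over patients
#' (repeated resources expand to the maximum cardinality, `medication_1`
#' up to `medication_m`, missing entries `NA`). Column order is
#' deterministic: demographics first, then condition, medication and
#' observation blocks. The result is invariant, up to row order, to the
#' order bundles were parsed in.
#'
#' @param resources List of `fhir_resource` objects (possibly concatenated
#'   over many bundles).
#' @param reference_date `Date` at which ages are computed; defaults to
#'   the latest event date found in the cohort (onset, authored, deceased
#'   or observation date), falling back to the latest birth date.
#' @return A `clinical_table` data frame keyed by `mrn`.
#' @export
flatten_to_table <- function(resources, reference_date = NULL) {
  demo_cols <- c("mrn", "gender", "birth_date", "age", "survived",
                 "deceased_date", "patient_json")
  if (!length(resources)) {
    out <- as.data.frame(stats::setNames(
      list(character(0), character(0), character(0), numeric(0), logical(0),
           character(0), character(0)), demo_cols), stringsAsFactors = FALSE)
    class(out) <- c("clinical_table", "data.frame")
    return(out)
  }
  mrns <- vapply(resources, `[[`, character(1), "subject_mrn")
  types <- vapply(resources, `[[`, character(1), "resource_type")
  pat_count <- table(mrns[types == "Patient"])
  if (any(pat_count > 1L)) {
    stop("duplicate patient: MRN ",
         paste(names(pat_count)[pat_count > 1L], collapse = ", "),
         " appears in more than one Patient resource")
  }

  if (is.null(reference_date)) {
    dates <- character(0)
    for (r in resources) {
      raw <- r$raw
      dates <- c(dates, raw$onsetDateTime, raw$authoredOn,
                 raw$deceasedDateTime, raw$effectiveDateTime)
    }
    dates <- substr(unlist(dates), 1L, 10L)
    if (!length(dates)) {
      dates <- vapply(resources[types == "Patient"],
                      function(r) r$raw$birthDate %||% NA_character_,
                      character(1))
      dates <- dates[!is.na(dates)]
    }
    reference_date <- if (length(dates)) max(as.Date(dates)) else Sys.Date()
  }

  groups <- split(resources, factor(mrns, levels = sort(unique(mrns))))
  rows <- lapply(groups, extract_patient_row, reference_date = reference_date)

  all_cols <- unique(unlist(lapply(rows, names)))
  ordered <- c(demo_cols,
               sort_block(all_cols, "^condition_"),
               sort_block(all_cols, "^medication_"),
               sort_block(all_cols, "^observation_"))
  ordered <- c(ordered, setdiff(all_cols, ordered))
  out <- do.call(rbind, lapply(rows, function(r) {
    for (nm in setdiff(ordered, names(r))) r[[nm]] <- NA
    r[, ordered, drop = FALSE]
  }))
  rownames(out) <- NULL
  class(out) <- c("clinical_table", "data.frame")
  out
}

# order repeated-resource columns by their index, then suffix
sort_block <- function(cols, prefix) {
  hit <- grep(prefix, cols, value = TRUE)
  if (!length(hit)) return(character(0))
  idx <- suppressWarnings(as.integer(sub("^[a-z]+_([0-9]+).*$", "\\1", hit)))
  idx[is.na(idx)] <- 0L
  hit[order(idx, hit)]
}

#' Columnar (Parquet) export of a clinical or merged table
#'
#' Writes through \pkg{arrow}; the round trip is lossless, including
#' JSON-string columns (preserved byte-identically). Paths ending in
#' `.csv` fall back to CSV.
#'
#' @param table A data frame.
#' @param path Output/input path (`.parquet` or `.csv`).
#' @return `write_columnar` returns `path` invisibly; `read_columnar` the
#'   data frame.
#' @export
write_columnar <- function(table, path) {
  if (grepl("\\.csv$", path)) {
    utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  } else {
    arrow::write_parquet(as.data.frame(table), path)
  }
  invisible(path)
}

#' @rdname write_columnar
#' @export
read_columnar <- function(path) {
  if (!file.exists(path)) stop("columnar file not found: ", path)
  df <- if (grepl("\\.csv$", path)) {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    out <- try(as.data.frame(arrow::read_parquet(path)), silent = TRUE)
    if (inherits(out, "try-error")) {
      stop("columnar format error reading ", path, ": ",
           attr(out, "condition")$message)
    }
    out
  }
  if (!is.data.frame(df)) stop("columnar format error: not a table: ", path)
  df
}
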