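# FHIR bundle parsing, flattening, columnar round trips

test_that("parse_bundle resolves subjects to the Patient MRN and skips the rest", {
  b <- make_bundle("P001", conditions = list(list(code = "BC")),
                   medications = c("Doxorubicin", "Epirubicin"),
                   observations = list(list(code = "wt", value = 70)),
                   extra_entries = list(list(resource = list(
                     resourceType = "Claim", id = "c1"))))
  res <- parse_bundle(b)
  expect_length(res, 5L)  # 1 Patient + 1 Condition + 2 Meds + 1 Obs
  mrns <- vapply(res, `[[`, character(1), "subject_mrn")
  expect_true(all(mrns == "P001"))
  expect_equal(attr(res, "skipped"), c(Claim = 1L))
  # resource conservation: emitted + skipped == entries
  expect_equal(length(res) + sum(attr(res, "skipped")), length(b$entry))
})

test_that("parse_bundle errors are specific", {
  b <- make_bundle("P001")
  b$entry[[1]]$resource$resourceType <- NULL
  expect_error(parse_bundle(b), "entry 1 missing resourceType")

  orphan <- make_bundle("P001", conditions = list(list(code = "BC")))
  orphan$entry[[2]]$resource$subject$reference <- "Patient/nobody"
  expect_error(parse_bundle(orphan), "orphan.*entry 2")

  expect_error(parse_bundle(list(resourceType = "Patient")), "not a FHIR Bundle")
})

test_that("parse_bundle resolves urn:uuid references and JSON string input", {
  b <- make_bundle("P002", conditions = list(list(code = "BC")))
  b$entry[[2]]$resource$subject$reference <- "urn:uuid:pat-P002"
  res <- parse_bundle(jsonlite::toJSON(b, auto_unbox = TRUE))
  expect_equal(res[[2]]$subject_mrn, "P002")
})

test_that("extract_patient_row flattens demographics, conditions and medications", {
  b <- make_bundle("P001", gender = "female", birth = "1970-01-01",
                   conditions = list(list(code = "BC")),
                   medications = "Doxorubicin")
  row <- extract_patient_row(parse_bundle(b),
                             reference_date = as.Date("2022-01-01"))
  expect_equal(row$mrn, "P001")
  expect_equal(row$gender, "female")
  expect_equal(row$birth_date, "1970-01-01")
  expect_equal(row$age, 52)
  expect_equal(row$condition_1, "BC")
  expect_equal(row$medication_1, "Doxorubicin")
  expect_true(row$survived)

  dead <- make_bundle("P002", deceased = "2021-06-01T00:00:00Z")
  row2 <- extract_patient_row(parse_bundle(dead))
  expect_false(row2$survived)

  none <- list(parse_bundle(make_bundle("P003",
                                        conditions = list(list(code = "X"))))[[2]])
  expect_error(extract_patient_row(none), "exactly one Patient")
})

test_that("flatten_to_table expands repeated resources to max cardinality", {
  bundles <- list(make_bundle("P001", medications = c("A", "B", "C")),
                  make_bundle("P002", medications = "Z"))
  res <- unlist(lapply(bundles, parse_bundle), recursive = FALSE)
  tab <- flatten_to_table(res)
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("medication_1", "medication_2", "medication_3") %in% names(tab)))
  expect_false("medication_4" %in% names(tab))
  p2 <- tab[tab$mrn == "P002", ]
  expect_equal(p2$medication_1, "Z")
  expect_true(is.na(p2$medication_2) && is.na(p2$medication_3))
})

test_that("flatten_to_table gives one row per MRN and rejects duplicates", {
  bundles <- lapply(sprintf("P%03d", 1:10), make_bundle)
  res <- unlist(lapply(bundles, parse_bundle), recursive = FALSE)
  tab <- flatten_to_table(res)
  expect_equal(nrow(tab), 10L)
  expect_equal(anyDuplicated(tab$mrn), 0L)

  dup <- unlist(lapply(list(make_bundle("P001"), make_bundle("P001")),
                       parse_bundle), recursive = FALSE)
  expect_error(flatten_to_table(dup), "duplicate patient.*P001")

  empty <- flatten_to_table(list())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("mrn", "gender", "birth_date", "age", "survived") %in%
                    names(empty)))
})

test_that("flattening is invariant to bundle order", {
  bundles <- list(make_bundle("P001", medications = c("A", "B")),
                  make_bundle("P002", conditions = list(list(code = "BC"))),
                  make_bundle("P003", observations = list(list(code = "wt",
                                                               value = 61))))
  res <- unlist(lapply(bundles, parse_bundle), recursive = FALSE)
  t1 <- flatten_to_table(res)
  set.seed(4)
  t2 <- flatten_to_table(sample(res))
  expect_equal(t1, t2)
})

test_that("no bundle value is silently dropped (leaf walk over fixture)", {
  b <- make_bundle("P007", gender = "female", birth = "1965-05-05",
                   deceased = "2021-06-01T00:00:00Z",
                   conditions = list(list(code = "BC",
                                          onset = "2020-03-04T00:00:00Z")),
                   medications = "Epirubicin",
                   observations = list(list(code = "weight", value = 63.5)))
  # mark an unmapped nested field that must survive via a _json column
  b$entry[[2]]$resource$clinicalStatus <- list(text = "active-xyz")
  row <- extract_patient_row(parse_bundle(b))
  cells <- unlist(lapply(row, as.character))
  findable <- function(v) any(vapply(cells, function(cell)
    grepl(v, cell, fixed = TRUE), logical(1)))
  leaves <- c("P007", "female", "1965-05-05", "2021-06-01T00:00:00Z", "BC",
              "2020-03-04T00:00:00Z", "Epirubicin", "63.5", "active-xyz")
  for (v in leaves) expect_true(findable(v), label = paste("leaf", v, "found"))
  # the unmapped field lives in exactly one cell (the condition json column)
  hits <- vapply(cells, function(cell) grepl("active-xyz", cell, fixed = TRUE),
                 logical(1))
  expect_equal(sum(hits), 1L)
  expect_match(names(row)[which(hits)], "^condition_1_json$")
})

test_that("columnar round trips are lossless, including JSON-string columns", {
  bundles <- lapply(sprintf("P%03d", 1:10), function(m)
    make_bundle(m, medications = "Doxorubicin",
                conditions = list(list(code = "BC"))))
  res <- unlist(lapply(bundles, parse_bundle), recursive = FALSE)
  tab <- flatten_to_table(res)
  tab$nested_json <- jsonlite::toJSON(list(a = 1, b = list(c = "x")),
                                      auto_unbox = TRUE)

  pq <- tempfile(fileext = ".parquet")
  write_columnar(tab, pq)
  rt <- read_columnar(pq)
  expect_equal(as.data.frame(rt), as.data.frame(tab))
  expect_identical(rt$nested_json[1], as.character(tab$nested_json[1]))

  # schema-only file for a 0-row table
  empty <- flatten_to_table(list())
  p0 <- tempfile(fileext = ".parquet")
  write_columnar(empty, p0)
  back <- read_columnar(p0)
  expect_equal(nrow(back), 0L)
  expect_equal(names(back), names(empty))

  # csv fallback
  cv <- tempfile(fileext = ".csv")
  write_columnar(tab[, c("mrn", "gender", "medication_1")], cv)
  expect_equal(read_columnar(cv)$mrn, tab$mrn)

  # unreadable columnar input -> format error
  junk <- tempfile(fileext = ".parquet")
  writeLines("not parquet", junk)
  expect_error(read_columnar(junk), "format error")
})
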