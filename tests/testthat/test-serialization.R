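test_that("JSON documents use the printed MIABIS codes as keys", {
  txt <- writeRecordSetJson(makeRecordSet(samples = list(
    Sample("S1", "Plasma"))))
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_identical(doc$samples[[1]][["MIABIS-SAMPLE-02"]], "Plasma")
  rs <- readRecordSetJson(txt)
  expect_identical(samples(rs)[["S1"]]@detailedSampleType, "Plasma")
})

test_that("the empty RecordSet round trips through empty component arrays", {
  txt <- writeRecordSetJson(makeRecordSet())
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_named(doc, c("biobanks", "collections", "donors", "events",
                      "samples"))
  expect_true(all(lengths(doc) == 0))
  expect_identical(readRecordSetJson(txt), makeRecordSet())
})

test_that("recorded-empty and not-recorded list attributes stay distinct", {
  rs <- makeRecordSet(samples = list(
    Sample("S1", "Serum", useRestrictions = character()),
    Sample("S2", "Serum")))
  txt <- writeRecordSetJson(rs)
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  s1 <- doc$samples[[1]]; s2 <- doc$samples[[2]]
  expect_true("MIABIS-SAMPLE-11" %in% names(s1))
  expect_length(s1[["MIABIS-SAMPLE-11"]], 0)
  expect_false("MIABIS-SAMPLE-11" %in% names(s2))
  back <- readRecordSetJson(txt)
  expect_identical(samples(back)[["S1"]]@useRestrictions, character())
  expect_null(samples(back)[["S2"]]@useRestrictions)
})

test_that("malformed documents fail with a JSON path", {
  expect_error(readRecordSetJson('{"gadgets": []}'), "unknown component")
  expect_error(
    readRecordSetJson('{"donors": [{"MIABIS-SAMPLEDONOR-99": "x"}]}'),
    "\\$\\.donors\\[1\\]")
  expect_error(
    readRecordSetJson(
      '{"donors": [{"MIABIS-SAMPLEDONOR-01": "D1", "MIABIS-SAMPLEDONOR-04": "2010-13"}]}'),
    "MIABIS-SAMPLEDONOR-04")
})

test_that("CSV headers are the attribute codes and both dialects round trip", {
  rs <- conformantFixture()
  d <- withr::local_tempdir()
  writeRecordSetCsv(rs, d, tabulate = FALSE)
  hdr <- names(read.csv(file.path(d, "sample.csv"), check.names = FALSE))
  expect_true(all(sprintf("MIABIS-SAMPLE-%02d", 1:11) %in% hdr))
  expect_identical(readRecordSetCsv(d), rs)

  d2 <- withr::local_tempdir()
  writeRecordSetCsv(rs, d2, tabulate = TRUE)
  hdr2 <- names(read.csv(file.path(d2, "sample.csv"), check.names = FALSE))
  expect_true("MIABIS-SAMPLE-11.commercial_use_restriction" %in% hdr2)
  expect_false("MIABIS-SAMPLE-11" %in% hdr2)
  expect_identical(readRecordSetCsv(d2), rs)
})

test_that("tabulation follows the three-valued Yes/No/Not-applicable scheme", {
  spec <- tabulatedColumnSpec("MIABIS-SAMPLE-11")
  expect_identical(nrow(spec), 6L)
  expect_identical(spec$column[1],
                   "MIABIS-SAMPLE-11.commercial_use_restriction")
  expect_identical(spec$value[1], "Commercial use restriction")

  rs <- makeRecordSet(samples = list(
    Sample("S1", "Serum",
           useRestrictions = c("Commercial use restriction")),
    Sample("S2", "Serum")))
  d <- withr::local_tempdir()
  writeRecordSetCsv(rs, d, tabulate = TRUE)
  tab <- read.csv(file.path(d, "sample.csv"), check.names = FALSE,
                  colClasses = "character")
  restrCols <- spec$column
  expect_identical(unname(unlist(tab[1, restrCols])),
                   c("Yes", rep("No", 5)))
  expect_identical(unname(unlist(tab[2, restrCols])),
                   rep("Not applicable", 6))
  expect_identical(readRecordSetCsv(d), rs)
})

test_that("content-diagnosis keywords tabulate; ICD codes go to the residual column", {
  rs <- makeRecordSet(samples = list(
    Sample("S1", "Serum", contentDiagnosis = c("Healthy", "C50.9"))))
  d <- withr::local_tempdir()
  writeRecordSetCsv(rs, d, tabulate = TRUE)
  tab <- read.csv(file.path(d, "sample.csv"), check.names = FALSE,
                  colClasses = "character")
  expect_identical(tab[["MIABIS-SAMPLE-10.healthy"]], "Yes")
  expect_identical(tab[["MIABIS-SAMPLE-10.unknown"]], "No")
  expect_identical(tab[["MIABIS-SAMPLE-10.icd10_codes"]], '["C50.9"]')
  expect_identical(readRecordSetCsv(d), rs)
})

test_that("corrupt tabulated cells are rejected", {
  rs <- makeRecordSet(samples = list(Sample("S1", "Serum",
    useRestrictions = character())))
  d <- withr::local_tempdir()
  writeRecordSetCsv(rs, d, tabulate = TRUE)
  p <- file.path(d, "sample.csv")
  txt <- readLines(p, encoding = "UTF-8")
  txt <- sub('"No"', '"Maybe"', txt)
  writeLines(txt, p, useBytes = TRUE)
  expect_error(readRecordSetCsv(d), "Yes/No/Not applicable")
})

test_that("canonical JSON is byte-stable and order-insensitive to input", {
  rs <- conformantFixture()
  expect_identical(writeRecordSetJson(rs), writeRecordSetJson(rs))
  shuffled <- makeRecordSet(
    donors = rev(donors(rs)), samples = rev(samples(rs)),
    events = rev(events(rs)), collections = collections(rs),
    biobanks = biobanks(rs))
  expect_identical(writeRecordSetJson(shuffled), writeRecordSetJson(rs))
})
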