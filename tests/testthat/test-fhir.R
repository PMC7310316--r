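test_that("the anatomical-site code lands on collection.bodySite.coding.code", {
  rs <- makeRecordSet(samples = list(
    Sample("S1", "Serum",
           anatomicalSite = AnatomicalSite("ICD-O-3", "3.2", "C50.9"))))
  fh <- toFhir(rs)
  doc <- fh$specimens[[1]]
  expect_identical(doc$resourceType, "Specimen")
  expect_identical(doc$collection$bodySite$coding$code, "C50.9")
  expect_identical(doc$collection$bodySite$coding$system, "ICD-O-3")
  expect_identical(doc$identifier$value, "S1")
})

test_that("donor records become Patient-shaped documents with mapped sex", {
  rs <- makeRecordSet(
    donors = list(SampleDonor("D1", "male", birthDate = "1975"),
                  SampleDonor("D2", "undifferentiated")),
    samples = list(Sample("S1", "Serum", donorRef = "D1")))
  fh <- toFhir(rs)
  p1 <- fh$patients[[1]]
  expect_identical(p1$resourceType, "Patient")
  expect_identical(p1$gender, "male")
  expect_identical(p1$birthDate, "1975")
  expect_identical(fh$patients[[2]]$gender, "other")
  expect_identical(fh$specimens[[1]]$subject$reference, "Patient/D1")
})

test_that("the coverage report partitions every attribute code exactly once", {
  fh <- toFhir(conformantFixture())
  cov <- fh$coverage
  expect_setequal(cov$code, miabisAttributes()$code)
  expect_false(anyDuplicated(cov$code) > 0)
  expect_true(all(!is.na(cov$targetPath[cov$mapped])))
  expect_true(all(is.na(cov$targetPath[!cov$mapped])))
  # the printed mapping is always present
  expect_identical(
    cov$targetPath[cov$code == "MIABIS-SAMPLE-07"],
    "Specimen.collection.bodySite.coding.code")
})

test_that("empty sets give zero documents and an empty coverage report", {
  fh <- toFhir(makeRecordSet())
  expect_length(fh$specimens, 0)
  expect_length(fh$patients, 0)
  expect_identical(nrow(fh$coverage), 0L)
})

test_that("broken mapping tables are rejected", {
  m <- defaultFhirMapping()
  m2 <- rbind(m, data.frame(miabisCode = "MIABIS-SAMPLE-03",
                            targetPath = m$targetPath[1],
                            transform = "identity"))
  expect_error(toFhir(conformantFixture(), m2), "path conflict")
  m3 <- m
  m3$miabisCode[1] <- "MIABIS-NOPE-01"
  expect_error(toFhir(conformantFixture(), m3), "unknown MIABIS code")
  m4 <- m[m$miabisCode != "MIABIS-SAMPLE-07", ]
  expect_error(toFhir(conformantFixture(), m4), "must retain")
})

test_that("emitted documents are serializable as well-formed JSON", {
  fh <- toFhir(conformantFixture())
  for (doc in c(fh$specimens, fh$patients)) {
    txt <- jsonlite::toJSON(doc, auto_unbox = TRUE)
    expect_silent(jsonlite::fromJSON(txt))
  }
})
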