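test_that("makeRecordSet builds ID indexes without validating constraints", {
  rs <- makeRecordSet(
    donors = list(SampleDonor("D1", "female")),
    samples = list(Sample("S1", "Serum", donorRef = "D1")))
  expect_length(donors(rs), 1)
  expect_length(samples(rs), 1)
  expect_named(samples(rs), "S1")

  # invalid records are constructible and loadable; only validation flags them
  bad <- makeRecordSet(donors = list(SampleDonor("D1", "hermaphrodite")))
  expect_s4_class(bad, "RecordSet")
  expect_identical(validateRecordSet(bad)$ruleId, "R-ENUM")

  empty <- makeRecordSet()
  expect_length(samples(empty), 0)
  expect_length(donors(empty), 0)
})

test_that("duplicate IDs are a construction error, scoped per collection for samples", {
  s1 <- Sample("S1", "Serum", collectionRef = "C1")
  s2 <- Sample("S1", "Plasma", collectionRef = "C1")
  expect_error(makeRecordSet(samples = list(s1, s2)), "duplicate sample ID")
  # same ID in different collections is allowed (per-collection scope)
  s2b <- Sample("S1", "Plasma", collectionRef = "C2")
  expect_silent(makeRecordSet(samples = list(s1, s2b)))
  # without a collection the scope is the whole set
  expect_error(
    makeRecordSet(samples = list(Sample("S1", "Serum"),
                                 Sample("S1", "Plasma"))),
    "duplicate sample ID")
  expect_error(
    makeRecordSet(donors = list(SampleDonor("D1", "male"),
                                SampleDonor("D1", "female"))),
    "duplicate donor ID")
})

test_that("resolveReferences reports dangling links and nothing else", {
  rs <- makeRecordSet(samples = list(Sample("S1", "Serum",
                                            donorRef = "D9")))
  rep <- resolveReferences(rs)
  expect_identical(nrow(rep), 1L)
  expect_identical(rep$field, "donorRef")
  expect_identical(rep$target, "D9")

  expect_identical(nrow(resolveReferences(conformantFixture())), 0L)

  # an unlinked event is a constraint matter, not a dangling reference
  rs2 <- makeRecordSet(events = list(Event("e1", ageAtEvent = 5,
                                           ageUnit = "years")))
  expect_identical(nrow(resolveReferences(rs2)), 0L)
  expect_true("R-EVENT-LINK" %in% validateRecordSet(rs2)$ruleId)
})

test_that("the model exposes exactly the printed attribute codes", {
  codes <- miabisAttributes()$code
  expect_setequal(codes, c(sprintf("MIABIS-SAMPLEDONOR-%02d", 1:4),
                           sprintf("MIABIS-SAMPLE-%02d", 1:11),
                           sprintf("MIABIS-EVENT-%02d", 1:4)))
  expect_false(anyDuplicated(codes) > 0)
})

test_that("scalar attributes never hold more than one value", {
  expect_error(SampleDonor("D1", sex = c("male", "female")), "length 1")
  expect_error(Sample("S1", detailedSampleType = c("Serum", "Plasma")),
               "length 1")
  expect_error(Event("e1", ageUnit = c("years", "months")), "length 1")
})

test_that("vocabularies are closed and bit-exact; canonicalization is opt-in", {
  expect_length(miabisVocabulary("MIABIS-SAMPLE-02"), 58)
  expect_true("Whole blood, dried (e.g., Guthrie cards)" %in%
                miabisVocabulary("MIABIS-SAMPLE-02"))
  temps <- miabisVocabulary("MIABIS-SAMPLE-03")
  expect_length(temps, 8)
  expect_true("Liquid nitrogen vapor phase" %in% temps)
  # canonical values use the Unicode minus and degree sign
  expect_true(any(grepl("−", temps)))

  rs <- makeRecordSet(samples = list(
    Sample("S1", "Serum", storageTemperature = "-18C to -35C")))
  expect_true("R-ENUM" %in% validateRecordSet(rs)$ruleId)
  fixed <- canonicalizeValue("MIABIS-SAMPLE-03", "-18C to -35C")
  expect_identical(fixed, "−18°C to −35°C")
  rs2 <- makeRecordSet(samples = list(
    Sample("S1", "Serum", storageTemperature = fixed)))
  expect_false("R-ENUM" %in% validateRecordSet(rs2)$ruleId)
  expect_identical(canonicalizeValue("MIABIS-SAMPLEDONOR-02", "Female"),
                   "female")
})

test_that("coded-string and ICD-10 format checks behave as documented", {
  expect_identical(isCodedString(c("D0001", "S-12_3.4", "bad id!", "")),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(isIcd10Code(c("C50.9", "A00", "U07.1", "X999", "c50")),
                   c(TRUE, TRUE, FALSE, FALSE, FALSE))
})
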