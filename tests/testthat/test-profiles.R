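test_that("the shipped locator profile loads and tightens only", {
  path <- system.file("extdata", "locator.profile.yaml", package = "miabis")
  p <- loadProfile(path)
  expect_s4_class(p, "MiabisProfile")
  expect_identical(p@name, "locator")
  expect_identical(p@cardinality, list(sample.donor = 1L))
  expect_identical(p@units[["MIABIS-EVENT-04"]], "years")
})

test_that("relaxing restrictions are rejected at load with the offender named", {
  expect_error(
    loadProfile(list(name = "bad", values = list(
      "MIABIS-SAMPLE-03" = c("RT", "−20°C exactly")))),
    "outside the printed vocabulary.*−20°C exactly")
  expect_error(
    loadProfile(list(name = "bad", required = "MIABIS-SAMPLE-99")),
    "unknown attribute code")
  expect_error(
    loadProfile(list(name = "bad", cardinality = list(sample.donor = 0))),
    "must be 1")
  expect_error(
    loadProfile(list(name = "bad",
                     cardinality = list("sample.granularity" = 1))),
    "unknown linkage edge")
  expect_error(
    loadProfile(list(name = "bad",
                     units = list("MIABIS-EVENT-03" = "years"))),
    "only MIABIS-EVENT-04")
})

test_that("donor-per-sample 1..n profile rejects what the generic model accepts", {
  p <- loadProfile(list(name = "locator",
                        cardinality = list(sample.donor = 1)))
  orphan <- makeRecordSet(samples = list(Sample("S1", "Serum")))
  expect_identical(nrow(validateRecordSet(orphan)), 0L)
  f <- validateAgainstProfile(orphan, p)
  expect_identical(f$ruleId, "P-CARD-sample.donor")
  expect_identical(f$severity, "error")
})

test_that("years-only age-unit profile rejects other units", {
  p <- loadProfile(list(name = "years",
                        units = list("MIABIS-EVENT-04" = "years")))
  d <- SampleDonor("D1", "male")
  e <- Event("e1", ageAtEvent = 6, ageUnit = "months",
             eventKind = "death", donorRef = "D1")
  rs <- makeRecordSet(donors = list(d), events = list(e))
  expect_identical(nrow(validateRecordSet(rs)), 0L)
  f <- validateAgainstProfile(rs, p)
  expect_identical(f$ruleId, "P-UNIT-MIABIS-EVENT-04")
})

test_that("promoted attributes and value restrictions report as P-findings", {
  p <- loadProfile(list(name = "strict",
                        required = c("MIABIS-SAMPLE-03"),
                        values = list("MIABIS-SAMPLE-02" = c("Serum",
                                                             "Plasma"))))
  rs <- makeRecordSet(samples = list(Sample("S1", "DNA")))
  f <- validateAgainstProfile(rs, p)
  expect_setequal(f$ruleId, c("P-REQ-MIABIS-SAMPLE-03",
                              "P-VALUE-MIABIS-SAMPLE-02"))
})

test_that("a profile with untouched restrictions changes nothing", {
  p <- loadProfile(list(name = "noop"))
  rs <- conformantFixture()
  expect_identical(validateAgainstProfile(rs, p), validateRecordSet(rs))
})

test_that("profile merge is union/intersection with conflict detection", {
  a <- loadProfile(list(name = "a",
                        cardinality = list(sample.donor = 1),
                        values = list("MIABIS-SAMPLE-02" = c("Serum",
                                                             "Plasma"))))
  b <- loadProfile(list(name = "b",
                        required = "MIABIS-SAMPLE-03",
                        values = list("MIABIS-SAMPLE-02" = c("Plasma",
                                                             "DNA"))))
  m <- mergeProfiles(a, b)
  expect_identical(m@values[["MIABIS-SAMPLE-02"]], "Plasma")
  expect_identical(m@cardinality, list(sample.donor = 1L))
  expect_identical(m@required, "MIABIS-SAMPLE-03")
  # commutative where restrictions are disjoint
  m2 <- mergeProfiles(b, a)
  expect_setequal(m2@values[["MIABIS-SAMPLE-02"]],
                  m@values[["MIABIS-SAMPLE-02"]])
  c1 <- loadProfile(list(name = "c1",
                         units = list("MIABIS-EVENT-04" = "years")))
  c2 <- loadProfile(list(name = "c2",
                         units = list("MIABIS-EVENT-04" = "months")))
  expect_error(mergeProfiles(c1, c2), "conflicting unit")
})
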