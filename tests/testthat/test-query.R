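queryFixture <- function() {
  makeRecordSet(
    donors = list(
      SampleDonor("D1", "female", birthDate = "1980-05-10"),
      SampleDonor("D2", "female"),
      SampleDonor("D3", "male")),
    samples = list(
      Sample("S1", "Serum", donorRef = "D1",
             useRestrictions = c("DNA use restriction")),
      Sample("S2", "Serum", donorRef = "D2"),
      Sample("S3", "Serum", donorRef = "D3"),
      Sample("S4", "Plasma", donorRef = "D1",
             useRestrictions = character())),
    events = list(
      Event("e1", eventDatetime = "2010-05-10T00:00:00",
            eventKind = "sampling", donorRef = "D1", sampleRef = "S1"),
      Event("e2", ageAtEvent = 360, ageUnit = "months",
            eventKind = "sampling", donorRef = "D2", sampleRef = "S2")))
}

test_that("conjunctive predicates select the expected samples and donors", {
  rs <- queryFixture()
  res <- evaluateQuery(rs, list(
    miabisPredicate("MIABIS-SAMPLE-02", "eq", "Serum"),
    miabisPredicate("MIABIS-SAMPLEDONOR-02", "eq", "female")))
  expect_identical(res$sampleIds, c("S1", "S2"))
  expect_identical(res$nSamples, 2L)
  expect_identical(res$nDonors, 2L)
})

test_that("the default missing policy excludes unrecorded attributes", {
  rs <- queryFixture()
  res <- evaluateQuery(rs, list(
    miabisPredicate("MIABIS-SAMPLE-11", "in", "DNA use restriction")))
  expect_identical(res$sampleIds, "S1")
  # under the permissive policy, unrecorded restriction lists pass
  res2 <- evaluateQuery(rs, list(
    miabisPredicate("MIABIS-SAMPLE-11", "in", "DNA use restriction",
                    missingPolicy = "pass")))
  expect_true(all(c("S2", "S3") %in% res2$sampleIds))
  # S4 records an empty list: recorded, but no matching value, so excluded
  expect_false("S4" %in% res2$sampleIds)
})

test_that("empty predicate lists match everything; results are deterministic", {
  rs <- queryFixture()
  res <- evaluateQuery(rs, list())
  expect_identical(res$sampleIds, c("S1", "S2", "S3", "S4"))
  expect_identical(res$nDonors, 3L)
})

test_that("event-derived ages answer range predicates in years", {
  rs <- queryFixture()
  # S1 via date arithmetic (30 at the 2010 anniversary), S2 via 360 months
  res <- evaluateQuery(rs, list(
    miabisPredicate("donor_age_at_sampling", "range", c(29, 31))))
  expect_identical(res$sampleIds, c("S1", "S2"))
})

test_that("ill-typed predicates are rejected", {
  expect_error(miabisPredicate("MIABIS-SAMPLE-99", "eq", "x"),
               "unknown predicate target")
  expect_error(miabisPredicate("MIABIS-SAMPLE-02", "range", c("A", "Z")),
               "only valid on dates and decimals")
  expect_error(miabisPredicate("age_at_event", "range", c(50, 20)),
               "inverted range")
  expect_error(miabisPredicate("MIABIS-SAMPLE-04", "range",
                               c("2015", "1990")),
               "inverted range")
  expect_error(evaluateQuery(queryFixture(), list(list(target = "x"))),
               "miabisPredicate")
})

test_that("recorded ages pass through deriveAge verbatim", {
  e <- Event("e1", ageAtEvent = 12.5, ageUnit = "months", donorRef = "D1")
  a <- deriveAge(e)
  expect_identical(a$age, 12.5)
  expect_identical(a$unit, "months")
  expect_identical(a$source, "recorded")
})

test_that("date-derived ages honour anniversaries and coarse precision", {
  d <- SampleDonor("D1", "female", birthDate = "1980-05-10")
  e <- Event("e1", eventDatetime = "2010-05-10T00:00:00", donorRef = "D1")
  a <- deriveAge(e, d)
  expect_identical(a$age, 30)
  expect_identical(a$unit, "years")

  # day before the anniversary
  e2 <- Event("e1", eventDatetime = "2010-05-09", donorRef = "D1")
  expect_identical(deriveAge(e2, d)$age, 29)

  # year-precision inputs give a whole-year difference
  dY <- SampleDonor("D1", "female", birthDate = "1980")
  eY <- Event("e1", eventDatetime = "2010", donorRef = "D1")
  aY <- deriveAge(eY, dY)
  expect_identical(aY$age, 30)
  expect_identical(aY$source, "year")

  expect_error(deriveAge(Event("e1"), d), "neither an age nor an event date")
  expect_error(deriveAge(Event("e1", eventDatetime = "1979"), d),
               "precedes")
  expect_error(deriveAge(Event("e1", eventDatetime = "2010"),
                         SampleDonor("D2", "male")),
               "birth date")
})

test_that("derived precision never exceeds the coarser input precision", {
  set.seed(21)
  lev <- c(year = 1, month = 2, day = 3, second = 4)
  for (i in 1:100) {
    b <- randomPt(c(1930, 1990))
    e <- randomPt(c(1991, 2020))
    a <- deriveAge(Event("e1", eventDatetime = e),
                   SampleDonor("D1", "male", birthDate = b))
    expect_lte(lev[[a$source]],
               min(lev[[ptPrecision(b)]], lev[[ptPrecision(e)]], 3))
  }
})
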