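test_that("the hand-audited fixture is fully conformant", {
  expect_identical(nrow(validateRecordSet(conformantFixture())), 0L)
})

test_that("time-encoding exclusivity and age-unit rules fire on events", {
  d <- SampleDonor("D1", "male", birthDate = "1975")
  both <- Event("e1", eventDatetime = "2010-01-01T00:00:00",
                ageAtEvent = 35, ageUnit = "years", donorRef = "D1")
  f <- validateRecordSet(makeRecordSet(donors = list(d),
                                       events = list(both)))
  expect_identical(errorFindings(f)$ruleId, "R-EVENT-XOR")

  noUnit <- Event("e2", ageAtEvent = 12.5, donorRef = "D1")
  f2 <- validateRecordSet(makeRecordSet(donors = list(d),
                                        events = list(noUnit)))
  expect_identical(errorFindings(f2)$ruleId, "R-EVENT-AGEUNIT")
})

test_that("a date-encoded event demands the linked donor's birth date", {
  d <- SampleDonor("D1", "male")  # no birth date
  e <- Event("e1", eventDatetime = "2010", eventKind = "death",
             donorRef = "D1")
  f <- validateRecordSet(makeRecordSet(donors = list(d), events = list(e)))
  expect_identical(errorFindings(f)$ruleId, "R-DONOR-BIRTHDATE")
  expect_identical(errorFindings(f)$component, "donor")

  # a partial (year-only) birth date satisfies the default rule ...
  d2 <- SampleDonor("D1", "male", birthDate = "1975")
  rs2 <- makeRecordSet(donors = list(d2),
                       events = list(Event("e1",
                                           eventDatetime = "2010-06-01",
                                           eventKind = "death",
                                           donorRef = "D1")))
  expect_identical(nrow(validateRecordSet(rs2)), 0L)
  # ... but not the strict variant for day-precision events
  strict <- validateRecordSet(rs2, strictBirthdate = TRUE)
  expect_identical(strict$ruleId, "R-DONOR-BIRTHDATE")

  # the requirement also reaches donors linked via the event's sample
  s <- Sample("S1", "Serum", donorRef = "D1")
  rs3 <- makeRecordSet(
    donors = list(SampleDonor("D1", "male")), samples = list(s),
    events = list(Event("e1", eventDatetime = "2010",
                        eventKind = "sampling", sampleRef = "S1")))
  expect_true("R-DONOR-BIRTHDATE" %in% validateRecordSet(rs3)$ruleId)
})

test_that("anatomical-site ontology pairing fires; free text alone does not", {
  s <- Sample("S1", "Serum",
              anatomicalSite = AnatomicalSite(code = "C50.9"))
  f <- validateRecordSet(makeRecordSet(samples = list(s)))
  expect_identical(errorFindings(f)$ruleId, "R-ANAT-PAIR")

  ok <- Sample("S1", "Serum",
               anatomicalSite = AnatomicalSite("ICD-O-3", "3.2", "C50.9"))
  expect_identical(nrow(validateRecordSet(makeRecordSet(
    samples = list(ok)))), 0L)

  freeOnly <- Sample("S1", "Serum",
                     anatomicalSite = AnatomicalSite(freeText = "unknown"))
  expect_identical(nrow(validateRecordSet(makeRecordSet(
    samples = list(freeOnly)))), 0L)

  # ontology given without version is also incomplete pairing
  halfPair <- Sample("S1", "Serum",
                     anatomicalSite = AnatomicalSite(ontology = "ICD-O-3"))
  expect_identical(
    errorFindings(validateRecordSet(makeRecordSet(
      samples = list(halfPair))))$ruleId,
    "R-ANAT-PAIR")
})

test_that("identifier syntax, ICD-10 format and chronology rules fire", {
  f <- validateRecordSet(makeRecordSet(donors = list(
    SampleDonor("no spaces allowed", "male"))))
  expect_identical(errorFindings(f)$ruleId, "R-ID-CODED")

  f2 <- validateRecordSet(makeRecordSet(samples = list(
    Sample("S1", "Serum", contentDiagnosis = c("Healthy", "X999")))))
  expect_identical(errorFindings(f2)$ruleId, "R-ICD10")

  rs <- makeRecordSet(
    donors = list(SampleDonor("D1", "male", birthDate = "1980")),
    events = list(Event("e1", eventDatetime = "1975",
                        eventKind = "death", donorRef = "D1")))
  f3 <- validateRecordSet(rs)
  expect_identical(f3$ruleId, "R-CHRONO")
  expect_identical(f3$severity, "warning")
})

test_that("validation is deterministic and stable in order", {
  rs <- mutateRecordSet(generateRecordSet(6, 2, 1, seed = 3),
                        "R-ENUM", seed = 5)
  f1 <- validateRecordSet(rs)
  f2 <- validateRecordSet(rs)
  expect_identical(f1, f2)
  expect_false(is.unsorted(order(f1$component, f1$recordId, f1$ruleId)))
})

test_that("adding an unrelated conformant record never removes a finding", {
  base <- mutateRecordSet(generateRecordSet(4, 2, 1, seed = 9),
                          "R-EVENT-XOR", seed = 2)
  before <- validateRecordSet(base)
  grown <- makeRecordSet(
    donors = c(donors(base), list(SampleDonor("DX99", "female"))),
    samples = samples(base), events = events(base),
    collections = collections(base), biobanks = biobanks(base))
  after <- validateRecordSet(grown)
  expect_true(all(findingKeys(before) %in% findingKeys(after)))
})

test_that("rule cards cite their constraint wording or mark design decisions", {
  card <- explainRule("R-EVENT-XOR")
  expect_match(card$anchor, "not both")
  expect_identical(card$severity, "error")
  expect_identical(explainRule("R-CHRONO")$anchor, "design decision")
  expect_error(explainRule("R-NOPE"), "unknown rule")
  for (id in listRules()) {
    card <- explainRule(id)
    expect_true(nzchar(card$anchor))
    expect_true(card$severity %in% c("error", "warning"))
  }
})

test_that("findings render to lines and to JSON", {
  f <- validateRecordSet(makeRecordSet(events = list(
    Event("e1", ageAtEvent = 2, donorRef = "D9"))))
  lines <- formatFindings(f)
  expect_true(any(grepl("R-REF", lines)))
  parsed <- jsonlite::fromJSON(findingsToJson(f))
  expect_setequal(parsed$ruleId, f$ruleId)
})
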