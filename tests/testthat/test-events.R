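test_that("registering kinds is guarded against duplicates and collisions", {
  on.exit(resetEventKinds())
  t <- EventKindTemplate("surgery",
    extras = list(list(name = "procedure_code", type = "text",
                       required = TRUE)),
    linkage = "donor_required")
  registerEventKind(t)
  expect_true("surgery" %in% names(eventKindRegistry()))
  expect_error(registerEventKind(t), "already registered")
  expect_silent(registerEventKind(t, replace = TRUE))
  expect_error(registerEventKind(EventKindTemplate("sampling")),
               "already registered")
  expect_error(
    EventKindTemplate("odd", extras = list(list(name = "Event ID"))),
    "collides")
})

test_that("a registered kind's required extras are enforced additively", {
  on.exit(resetEventKinds())
  registerEventKind(EventKindTemplate("surgery",
    extras = list(list(name = "procedure_code", type = "text",
                       required = TRUE)),
    linkage = "donor_required"))
  d <- SampleDonor("D1", "male")
  bad <- Event("e1", ageAtEvent = 50, ageUnit = "years",
               eventKind = "surgery", donorRef = "D1")
  f <- validateRecordSet(makeRecordSet(donors = list(d),
                                       events = list(bad)))
  expect_identical(f$ruleId, "R-TMPL-REQ")
  good <- Event("e1", ageAtEvent = 50, ageUnit = "years",
                eventKind = "surgery",
                extraAttributes = list(procedure_code = "OP-123"),
                donorRef = "D1")
  expect_identical(nrow(validateRecordSet(makeRecordSet(
    donors = list(d), events = list(good)))), 0L)

  # generic rules still apply to templated kinds (additive, not subtractive)
  both <- Event("e2", eventDatetime = "2010", ageAtEvent = 50,
                ageUnit = "years", eventKind = "surgery",
                extraAttributes = list(procedure_code = "OP-123"),
                donorRef = "D1")
  d2 <- SampleDonor("D1", "male", birthDate = "1950")
  f2 <- validateRecordSet(makeRecordSet(donors = list(d2),
                                        events = list(both)))
  expect_true("R-EVENT-XOR" %in% f2$ruleId)
})

test_that("the three built-in templates behave as in the use-case examples", {
  d <- SampleDonor("D1", "female")
  diag <- Event("e1", ageAtEvent = 54, ageUnit = "years",
                eventKind = "disease_diagnosis",
                extraAttributes = list(diagnosis_code = "C50.9"),
                donorRef = "D1")
  expect_identical(nrow(validateRecordSet(makeRecordSet(
    donors = list(d), events = list(diag)))), 0L)

  # diagnosis code outside the content-diagnosis value space
  badDiag <- Event("e1", ageAtEvent = 54, ageUnit = "years",
                   eventKind = "disease_diagnosis",
                   extraAttributes = list(diagnosis_code = "banana"),
                   donorRef = "D1")
  expect_identical(validateRecordSet(makeRecordSet(
    donors = list(d), events = list(badDiag)))$ruleId, "R-TMPL-REQ")

  # sampling demands a sample reference
  samplingNoRef <- Event("e1", ageAtEvent = 30, ageUnit = "years",
                         eventKind = "sampling", donorRef = "D1")
  expect_identical(validateRecordSet(makeRecordSet(
    donors = list(d), events = list(samplingNoRef)))$ruleId,
    "R-TMPL-LINK")

  # at most one death event per donor (warning severity)
  deaths <- list(
    Event("e1", ageAtEvent = 80, ageUnit = "years", eventKind = "death",
          donorRef = "D1"),
    Event("e2", ageAtEvent = 81, ageUnit = "years", eventKind = "death",
          donorRef = "D1"))
  f <- validateRecordSet(makeRecordSet(donors = list(d), events = deaths))
  expect_identical(f$ruleId, "R-DEATH-UNIQUE")
  expect_identical(f$severity, "warning")
})

test_that("unregistered kinds warn and still get generic validation", {
  d <- SampleDonor("D1", "male")
  e <- Event("e1", ageAtEvent = 5, eventKind = "mystery", donorRef = "D1")
  f <- validateRecordSet(makeRecordSet(donors = list(d), events = list(e)))
  expect_setequal(f$ruleId, c("R-EVENT-KIND", "R-EVENT-AGEUNIT"))
  expect_identical(f$severity[f$ruleId == "R-EVENT-KIND"], "warning")
})

test_that("templates load from the same config dialect as profiles", {
  on.exit(resetEventKinds())
  cfg <- list(kind = "follow_up", linkage = "donor_required",
              extras = list(list(name = "outcome", type = "enum",
                                 allowed = c("alive", "dead"),
                                 required = TRUE)))
  t <- EventKindTemplate(cfg$kind, cfg$extras, cfg$linkage)
  registerEventKind(t)
  d <- SampleDonor("D1", "male")
  e <- Event("e1", ageAtEvent = 3, ageUnit = "years",
             eventKind = "follow_up",
             extraAttributes = list(outcome = "cured"), donorRef = "D1")
  f <- validateRecordSet(makeRecordSet(donors = list(d), events = list(e)))
  expect_identical(f$ruleId, "R-TMPL-REQ")
  expect_match(f$message, "disallowed value")
})
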