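# Shared fixtures and independent oracles for the test suite.

# Hand-audited conformant fixture: 2 donors, 3 samples, 3 events.
# D0001 has a day-precision birth date and a date-encoded sampling event;
# D0002 has no birth date and only age-encoded events.
conformantFixture <- function() {
  makeRecordSet(
    biobanks = list(BiobankStub("B1", "Fixture biobank")),
    collections = list(SampleCollectionStub("C1", "Fixture collection",
                                            "B1")),
    donors = list(
      SampleDonor("D0001", "female", c("medical records"),
                  birthDate = "1980-05-10"),
      SampleDonor("D0002", "male")),
    samples = list(
      Sample("S0001", "Serum", storageTemperature = "RT",
             creationDatetime = "2005-06",
             anatomicalSite = AnatomicalSite("ICD-O-3", "3.2", "C50.9"),
             contentDiagnosis = c("C50.9"),
             useRestrictions = c("Commercial use restriction"),
             donorRef = "D0001", collectionRef = "C1"),
      Sample("S0002", "Plasma", useRestrictions = character(),
             donorRef = "D0001", collectionRef = "C1"),
      Sample("S0003", "DNA", donorRef = "D0002", collectionRef = "C1")),
    events = list(
      Event("e1a2b3c4", eventDatetime = "2005-06-15",
            eventKind = "sampling", donorRef = "D0001", sampleRef = "S0001"),
      Event("e2b3c4d5", ageAtEvent = 54, ageUnit = "years",
            eventKind = "disease_diagnosis",
            extraAttributes = list(diagnosis_code = "C50.9"),
            donorRef = "D0001"),
      Event("e3c4d5e6", ageAtEvent = 30.5, ageUnit = "years",
            eventKind = "sampling", donorRef = "D0002",
            sampleRef = "S0003")))
}

errorFindings <- function(findings) findings[findings$severity == "error", ]

# ---------------------------------------------------------------------------
# Independent brute-force query oracle: flattens every sample into explicit
# value bags and filters them with plain loops.  Deliberately written
# against the public record API only, with its own control flow.

.oracleBag <- function(rs, s) {
  ds <- donors(rs); es <- events(rs)
  d <- if (!is.na(s@donorRef) && s@donorRef %in% names(ds))
    ds[[s@donorRef]] else NULL
  linked <- list()
  for (e in es) {
    direct <- !is.na(e@sampleRef) && e@sampleRef == s@sampleId
    viaDonor <- !is.null(d) && !is.na(e@donorRef) &&
      e@donorRef == d@donorId
    if (direct || viaDonor) linked[[length(linked) + 1L]] <- e
  }
  list(sample = s, donor = d, events = linked)
}

.oracleAgeYears <- function(e, d) {
  if (!is.na(e@ageAtEvent)) {
    conv <- c(years = 1, months = 1 / 12, weeks = 1 / 52.1775,
              days = 1 / 365.25)
    if (is.na(e@ageUnit) || !e@ageUnit %in% names(conv)) return(numeric())
    return(e@ageAtEvent * conv[[e@ageUnit]])
  }
  if (is.null(e@eventDatetime) || is.null(d) || is.null(d@birthDate))
    return(numeric())
  out <- tryCatch(deriveAge(e, d)$age, error = function(err) numeric())
  out
}

.oracleValues <- function(bag, target) {
  s <- bag$sample; d <- bag$donor
  pick <- function(x) if (is.null(x)) c() else x[!is.na(x)]
  if (target == "age_at_event" || target == "donor_age_at_sampling") {
    out <- c()
    for (e in bag$events) {
      if (target == "donor_age_at_sampling" &&
          !(identical(e@eventKind, "sampling") && !is.na(e@sampleRef) &&
              e@sampleRef == s@sampleId)) next
      out <- c(out, .oracleAgeYears(e, d))
    }
    return(out)
  }
  if (target == "MIABIS-SAMPLE-10" && !is.null(s@contentDiagnosis))
    return(s@contentDiagnosis)
  if (target == "MIABIS-SAMPLE-11" && !is.null(s@useRestrictions))
    return(s@useRestrictions)
  if (target == "MIABIS-SAMPLEDONOR-03" && !is.null(d) &&
      !is.null(d@dataCategories))
    return(d@dataCategories)
  a <- s@anatomicalSite
  switch(target,
    "MIABIS-SAMPLE-01" = pick(s@sampleId),
    "MIABIS-SAMPLE-02" = pick(s@detailedSampleType),
    "MIABIS-SAMPLE-03" = pick(s@storageTemperature),
    "MIABIS-SAMPLE-04" = if (is.null(s@creationDatetime)) c() else
      formatPartialTimestamp(s@creationDatetime),
    "MIABIS-SAMPLE-07" = if (is.null(a)) c() else pick(a@code),
    "MIABIS-SAMPLE-10" = pick(s@contentDiagnosis),
    "MIABIS-SAMPLE-11" = pick(s@useRestrictions),
    "MIABIS-SAMPLEDONOR-01" = if (is.null(d)) c() else pick(d@donorId),
    "MIABIS-SAMPLEDONOR-02" = if (is.null(d)) c() else pick(d@sex),
    "MIABIS-SAMPLEDONOR-03" = if (is.null(d)) c() else
      pick(d@dataCategories),
    "MIABIS-SAMPLEDONOR-04" = if (is.null(d) || is.null(d@birthDate)) c()
      else formatPartialTimestamp(d@birthDate),
    "MIABIS-EVENT-03" = {
      out <- c()
      for (e in bag$events) if (!is.na(e@ageAtEvent))
        out <- c(out, e@ageAtEvent)
      out
    },
    "MIABIS-EVENT-04" = {
      out <- c()
      for (e in bag$events) if (!is.na(e@ageUnit)) out <- c(out, e@ageUnit)
      out
    },
    stop("oracle has no extractor for ", target))
}

.oracleRecorded <- function(bag, target) {
  s <- bag$sample; d <- bag$donor
  if (target == "MIABIS-SAMPLE-10") return(!is.null(s@contentDiagnosis))
  if (target == "MIABIS-SAMPLE-11") return(!is.null(s@useRestrictions))
  if (target == "MIABIS-SAMPLEDONOR-03")
    return(!is.null(d) && !is.null(d@dataCategories))
  length(.oracleValues(bag, target)) > 0
}

.oracleHolds <- function(bag, p) {
  vals <- .oracleValues(bag, p$target)
  rec <- .oracleRecorded(bag, p$target)
  if (p$op == "exists") return(rec)
  if (p$op == "missing") return(!rec)
  if (!rec) return(p$missingPolicy == "pass")
  if (length(vals) == 0) return(FALSE)
  ok <- FALSE
  for (v in vals) {
    ok <- ok || switch(p$op,
      eq = if (p$type == "timestamp")
        ptCompare(parsePartialTimestamp(v),
                  parsePartialTimestamp(p$operand)) == 0
      else v == p$operand,
      "in" = as.character(v) %in% as.character(p$operand),
      range = if (p$type == "timestamp") {
        pt <- parsePartialTimestamp(v)
        ptCompare(pt, parsePartialTimestamp(p$operand[1])) >= 0 &&
          ptCompare(pt, parsePartialTimestamp(p$operand[2])) <= 0
      } else {
        as.numeric(v) >= p$operand[1] && as.numeric(v) <= p$operand[2]
      })
  }
  ok
}

bruteForceQuery <- function(rs, preds) {
  ids <- character()
  dids <- character()
  for (s in samples(rs)) {
    bag <- .oracleBag(rs, s)
    all_ok <- TRUE
    for (p in preds) all_ok <- all_ok && .oracleHolds(bag, p)
    if (all_ok) {
      ids <- c(ids, s@sampleId)
      if (!is.null(bag$donor)) dids <- c(dids, bag$donor@donorId)
    }
  }
  list(sampleIds = sort(ids, method = "radix"), nSamples = length(ids),
       nDonors = length(unique(dids)))
}

# random predicate drawn from a small pool of well-typed shapes
randomPredicate <- function() {
  shape <- sample(1:8, 1)
  mp <- sample(c("fail", "pass"), 1)
  switch(shape,
    miabisPredicate("MIABIS-SAMPLE-02", "eq",
                    sample(miabisVocabulary("MIABIS-SAMPLE-02"), 1), mp),
    miabisPredicate("MIABIS-SAMPLE-02", "in",
                    sample(miabisVocabulary("MIABIS-SAMPLE-02"), 5), mp),
    miabisPredicate("MIABIS-SAMPLEDONOR-02", "eq",
                    sample(c("male", "female"), 1), mp),
    miabisPredicate("MIABIS-SAMPLE-11", "in",
                    sample(miabisVocabulary("MIABIS-SAMPLE-11"), 2), mp),
    miabisPredicate("age_at_event", "range",
                    sort(round(runif(2, 0, 90), 1)), mp),
    miabisPredicate("MIABIS-SAMPLE-04", "range",
                    c("1990", "2015"), mp),
    miabisPredicate("MIABIS-SAMPLE-10", "exists"),
    miabisPredicate("MIABIS-SAMPLEDONOR-04", "missing"))
}

# ---------------------------------------------------------------------------
# Independent calendar oracle for age derivation, using base-R Date
# arithmetic at day precision and plain integer arithmetic at coarser
# precisions.

oracleAgeFromDates <- function(birth, event) {
  lev <- function(p) c(year = 1, month = 2, day = 3, second = 4)[[p]]
  level <- min(lev(ptPrecision(birth)), lev(ptPrecision(event)))
  if (level == 1) return(event@year - birth@year)
  if (level == 2) {
    months <- (event@year * 12 + event@month) -
      (birth@year * 12 + birth@month)
    return(months %/% 12)
  }
  bd <- as.Date(sprintf("%04d-%02d-%02d", birth@year, birth@month,
                        birth@day))
  ed <- as.Date(sprintf("%04d-%02d-%02d", event@year, event@month,
                        event@day))
  y <- as.integer(format(ed, "%Y")) - as.integer(format(bd, "%Y"))
  if (format(ed, "%m-%d") < format(bd, "%m-%d")) y <- y - 1L
  y
}

# random partial timestamp for property tests
randomPt <- function(yearRange = c(1930, 2020)) {
  y <- sample(yearRange[1]:yearRange[2], 1)
  prec <- sample(1:4, 1)
  m <- sample(1:12, 1); d <- sample(1:28, 1)
  switch(prec,
    PartialTimestamp(y),
    PartialTimestamp(y, m),
    PartialTimestamp(y, m, d),
    PartialTimestamp(y, m, d, sample(0:23, 1), sample(0:59, 1),
                     sample(0:59, 1)))
}

# random tightening-only profile over the generic model
randomProfile <- function() {
  spec <- list(name = "random")
  if (runif(1) < 0.5)
    spec$cardinality <- setNames(
      as.list(rep(1, 1)),
      sample(c("sample.donor", "sample.collection", "event.sample",
               "event.donor", "collection.biobank"), 1))
  if (runif(1) < 0.5)
    spec$required <- sample(c("MIABIS-SAMPLEDONOR-03",
                              "MIABIS-SAMPLEDONOR-04", "MIABIS-SAMPLE-03",
                              "MIABIS-SAMPLE-04", "MIABIS-SAMPLE-10",
                              "MIABIS-SAMPLE-11"), sample(1:2, 1))
  if (runif(1) < 0.5) {
    code <- sample(c("MIABIS-SAMPLE-02", "MIABIS-SAMPLE-03",
                     "MIABIS-SAMPLEDONOR-02", "MIABIS-SAMPLE-11"), 1)
    vocab <- miabisVocabulary(code)
    spec$values <- setNames(
      list(sample(vocab, max(1, length(vocab) %/% 2))), code)
  }
  if (runif(1) < 0.3)
    spec$units <- list("MIABIS-EVENT-04" = sample(
      miabisVocabulary("MIABIS-EVENT-04"), 2))
  loadProfile(spec)
}

findingKeys <- function(f) {
  sprintf("%s|%s|%s|%s", f$ruleId, f$component, f$recordId, f$message)
}
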