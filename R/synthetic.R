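# Synthetic record-set generation and rule-targeted mutation.
#
# The generator produces record sets that conform to the generic model (and
# the built-in event-kind templates) by construction, mixing partial-date
# precisions and both event time encodings; the mutator breaks exactly one
# registered rule so the validation engine's sensitivity can be tested
# knockout-style.  Donor and sample IDs follow the "D0001"/"S0001" style;
# event IDs are random hex, mirroring the standard's note that event IDs
# are random identifiers created by the database implementation.

.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a scalar integer seed is mandatory")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  force(expr)
}

.countVector <- function(x, n, label) {
  if (is.function(x)) out <- x(n)
  else if (length(x) == 1L) out <- rep(x, n)
  else out <- x
  out <- as.integer(out)
  if (length(out) != n || anyNA(out) || any(out < 0L))
    stop("invalid ", label, " distribution")
  out
}

.randHex <- function(n = 12L)
  paste(sample(c(0:9, letters[1:6]), n, replace = TRUE), collapse = "")

.ICD_POOL <- c("C50.9", "C61", "E11.9", "I25.1", "J45", "K70.3", "C18.7",
               "G30.9", "N18.5", "M05.79")

# weights toward common biobank holdings for the realism preset; no claim
# of epidemiological realism
.COMMON_TYPES <- c("Whole blood", "Serum", "Plasma", "DNA", "Buffy coat",
                   "Tissue (FFPE)", "Urine")

.randomPartialDate <- function(yearRange, precWeights = c(.4, .2, .3, .1)) {
  y <- sample(yearRange[1]:yearRange[2], 1L)
  prec <- sample(c("year", "month", "day", "second"), 1L, prob = precWeights)
  m <- sample(1:12, 1L)
  d <- sample(1:28, 1L)
  switch(prec,
    year = PartialTimestamp(y),
    month = PartialTimestamp(y, m),
    day = PartialTimestamp(y, m, d),
    second = PartialTimestamp(y, m, d, sample(0:23, 1L), sample(0:59, 1L),
                              sample(0:59, 1L)))
}

#' Generate a conformant synthetic RecordSet
#'
#' Produces `nDonors` donors with `samplesPerDonor` samples each and
#' `eventsPerSample` events per sample, linked into one synthetic biobank
#' with two collections.  Attribute values are drawn uniformly from the
#' printed vocabularies (`realism = TRUE` skews sample types toward common
#' holdings); partial-date precisions are mixed deliberately; both the
#' age-at-event and the event-date time encodings occur, with a birth date
#' supplied whenever a date-encoded event demands one.  The result passes
#' [validateRecordSet()] with zero findings, by construction.
#'
#' @param nDonors number of donors (0 gives an empty set).
#' @param samplesPerDonor,eventsPerSample a constant count or a
#'   `function(n)` returning one count per donor/sample.
#' @param seed mandatory integer seed; identical seeds give identical
#'   canonical serializations.
#' @param realism logical; skew sample types toward common holdings.
#' @return a [RecordSet-class].
#' @examples
#' rs <- generateRecordSet(10, samplesPerDonor = 2, eventsPerSample = 1,
#'                         seed = 42)
#' rs
#' nrow(validateRecordSet(rs))
#' @export
generateRecordSet <- function(nDonors, samplesPerDonor = 2,
                              eventsPerSample = 1, seed,
                              realism = FALSE) {
  stopifnot(nDonors >= 0)
  if (nDonors == 0) return(makeRecordSet())
  .withSeed(seed, {
    nSamp <- .countVector(samplesPerDonor, nDonors, "samplesPerDonor")

    bb <- BiobankStub("B0001", "Synthetic biobank")
    colls <- list(SampleCollectionStub("C0001", "Synthetic collection 1",
                                       "B0001"),
                  SampleCollectionStub("C0002", "Synthetic collection 2",
                                       "B0001"))

    donorsL <- list(); samplesL <- list(); eventsL <- list()
    usedEventIds <- character()
    donorHasDeath <- logical(nDonors)
    sid <- 0L

    # per-donor time-encoding mode; force both modes to occur
    dateMode <- stats::runif(nDonors) < 0.6
    dateMode[1] <- TRUE
    if (nDonors >= 2) dateMode[2] <- FALSE

    for (i in seq_len(nDonors)) {
      did <- sprintf("D%04d", i)
      birth <- if (dateMode[i] || stats::runif(1) < 0.5)
        .randomPartialDate(c(1930, 1999)) else NULL
      u <- stats::runif(1)
      dataCat <- if (u < 0.3) NULL
        else if (u < 0.4) character()
        else sample(.VOCAB$data_categories, sample(1:3, 1L))
      donorsL[[i]] <- SampleDonor(did, sample(.VOCAB$sex, 1L), dataCat,
                                  birth)

      for (j in seq_len(nSamp[i])) {
        sid <- sid + 1L
        sId <- sprintf("S%04d", sid)
        typePool <- if (realism) .COMMON_TYPES else
          .VOCAB$detailed_sample_type
        creation <- if (stats::runif(1) < 0.7) {
          minY <- if (is.null(birth)) 1990L else birth@year + 1L
          .randomPartialDate(c(minY, 2019))
        } else NULL
        anat <- if (sid == 1L || stats::runif(1) < 0.25) {
          AnatomicalSite("ICD-O-3", "3.2", sample(.ICD_POOL, 1L),
                         description = if (stats::runif(1) < 0.5)
                           "synthetic topography" else NA)
        } else if (stats::runif(1) < 0.1) {
          AnatomicalSite(freeText = "site unknown")
        } else NULL
        cdU <- stats::runif(1)
        contentDx <- if (cdU < 0.55) NULL
          else if (cdU < 0.65) character()
          else unique(c(
            if (stats::runif(1) < 0.5)
              sample(.VOCAB$content_diagnosis_keywords, 1L),
            if (stats::runif(1) < 0.7) sample(.ICD_POOL, 1L)))
        urU <- stats::runif(1)
        useRestr <- if (urU < 0.5) NULL
          else if (urU < 0.6) character()
          else sample(.VOCAB$use_restrictions, sample(1:2, 1L))
        samplesL[[sid]] <- Sample(
          sId, sample(typePool, 1L),
          storageTemperature = if (stats::runif(1) < 0.8)
            sample(.VOCAB$storage_temperature, 1L) else NA,
          creationDatetime = creation, anatomicalSite = anat,
          contentDiagnosis = contentDx, useRestrictions = useRestr,
          donorRef = did, collectionRef = sample(c("C0001", "C0002"), 1L))

        nEv <- .countVector(eventsPerSample, 1L, "eventsPerSample")
        for (k in seq_len(nEv)) {
          repeat {
            eId <- .randHex()
            if (!eId %in% usedEventIds) break
          }
          usedEventIds <- c(usedEventIds, eId)
          kindU <- stats::runif(1)
          kind <- if (kindU < 0.6) "sampling"
            else if (kindU < 0.85 || donorHasDeath[i]) "disease_diagnosis"
            else "death"
          if (kind == "death") donorHasDeath[i] <- TRUE
          extras <- switch(kind,
            disease_diagnosis = list(diagnosis_code =
              if (stats::runif(1) < 0.8) sample(.ICD_POOL, 1L)
              else sample(.VOCAB$content_diagnosis_keywords, 1L)),
            death = if (stats::runif(1) < 0.5)
              list(cause_of_death_code = sample(.ICD_POOL, 1L)) else list(),
            list())
          if (dateMode[i]) {
            ev <- .randomPartialDate(c(birth@year + 1L, 2019))
            eventsL[[length(eventsL) + 1L]] <- Event(
              eId, eventDatetime = ev, eventKind = kind, extraAttributes = extras,
              donorRef = did, sampleRef = sId)
          } else {
            unit <- sample(c("years", "years", "months", "weeks", "days",
                             "gestational weeks"), 1L)
            age <- switch(unit,
              years = round(stats::runif(1, 0.5, 80), 1),
              months = round(stats::runif(1, 1, 36), 1),
              weeks = round(stats::runif(1, 1, 104), 1),
              days = round(stats::runif(1, 1, 365), 0),
              `gestational weeks` = round(stats::runif(1, 20, 41), 1))
            eventsL[[length(eventsL) + 1L]] <- Event(
              eId, ageAtEvent = age, ageUnit = unit, eventKind = kind,
              extraAttributes = extras, donorRef = did, sampleRef = sId)
          }
        }
      }
    }
    makeRecordSet(donors = donorsL, samples = samplesL, events = eventsL,
                  collections = colls, biobanks = list(bb))
  })
}

.pickOne <- function(candidates, ruleId) {
  if (!length(candidates))
    stop("rule ", ruleId, " is not mutable on this fixture: ",
         "no suitable record to break")
  if (length(candidates) == 1L) candidates[[1]] else sample(candidates, 1L)
}

#' Break exactly one validation rule in a conformant RecordSet
#'
#' Returns a copy of `rs` modified so that [validateRecordSet()] reports
#' exactly the findings of `ruleId` (plus any entailed findings declared in
#' the rule's metadata — see [ruleEntailments()]).  Errors explicitly when
#' the fixture carries no record the rule could be broken on; never a
#' silent no-op.
#'
#' @param rs a conformant [RecordSet-class].
#' @param ruleId a registered rule id (see [listRules()]).
#' @param seed integer seed choosing the record to break.
#' @return the mutated [RecordSet-class].
#' @examples
#' rs <- generateRecordSet(5, seed = 1)
#' bad <- mutateRecordSet(rs, "R-EVENT-XOR", seed = 7)
#' unique(validateRecordSet(bad)$ruleId)
#' @export
mutateRecordSet <- function(rs, ruleId, seed) {
  stopifnot(is(rs, "RecordSet"))
  if (!ruleId %in% names(.RULES)) stop("unknown rule id '", ruleId, "'")
  .withSeed(seed, {
    ds <- rs@donors; ss <- rs@samples; es <- rs@events
    dateEvents <- which(vapply(es, function(e) !is.null(e@eventDatetime),
                               logical(1)))
    ageEvents <- which(vapply(es, function(e) !is.na(e@ageAtEvent),
                              logical(1)))
    mod <- function(obj, slotName, value) {
      slot(obj, slotName, check = FALSE) <- value
      obj
    }
    switch(ruleId,
      "R-REF" = {
        i <- .pickOne(which(vapply(es, function(e)
          !is.na(e@sampleRef) && !is.na(e@donorRef), logical(1))), ruleId)
        es[[i]] <- mod(es[[i]], "donorRef", "ZZMISSING")
      },
      "R-DONOR-REQ" = {
        i <- .pickOne(seq_along(ds), ruleId)
        ds[[i]] <- mod(ds[[i]], "sex", NA_character_)
      },
      "R-SAMPLE-REQ" = {
        i <- .pickOne(seq_along(ss), ruleId)
        ss[[i]] <- mod(ss[[i]], "detailedSampleType", NA_character_)
      },
      "R-EVENT-REQ" = {
        i <- .pickOne(seq_along(es), ruleId)
        es[[i]] <- mod(es[[i]], "eventId", NA_character_)
      },
      "R-ID-CODED" = {
        i <- .pickOne(seq_along(ds), ruleId)
        oldId <- ds[[i]]@donorId
        newId <- paste0("bad id ", oldId, "!")
        ds[[i]] <- mod(ds[[i]], "donorId", newId)
        ss <- lapply(ss, function(s)
          if (identical(s@donorRef, oldId)) mod(s, "donorRef", newId) else s)
        es <- lapply(es, function(e)
          if (identical(e@donorRef, oldId)) mod(e, "donorRef", newId) else e)
      },
      "R-EVENT-XOR" = {
        i <- .pickOne(dateEvents, ruleId)
        es[[i]] <- mod(mod(es[[i]], "ageAtEvent", 35), "ageUnit", "years")
      },
      "R-EVENT-AGEUNIT" = {
        i <- .pickOne(ageEvents, ruleId)
        es[[i]] <- mod(es[[i]], "ageUnit", NA_character_)
      },
      "R-DONOR-BIRTHDATE" = {
        i <- .pickOne(dateEvents, ruleId)
        did <- .eventDonorId(es[[i]], rs)
        if (is.na(did)) stop("rule ", ruleId, " is not mutable here")
        ds[[did]] <- mod(ds[[did]], "birthDate", NULL)
      },
      "R-ANAT-PAIR" = {
        i <- .pickOne(which(vapply(ss, function(s)
          !is.null(s@anatomicalSite) && !is.na(s@anatomicalSite@code),
          logical(1))), ruleId)
        a <- ss[[i]]@anatomicalSite
        a <- mod(mod(a, "ontology", NA_character_), "ontologyVersion",
                 NA_character_)
        ss[[i]] <- mod(ss[[i]], "anatomicalSite", a)
      },
      "R-EVENT-LINK" = {
        i <- .pickOne(seq_along(es), ruleId)
        es[[i]] <- mod(mod(es[[i]], "donorRef", NA_character_),
                       "sampleRef", NA_character_)
      },
      "R-ENUM" = {
        i <- .pickOne(seq_along(ds), ruleId)
        ds[[i]] <- mod(ds[[i]], "sex", "MALE")
      },
      "R-ICD10" = {
        i <- .pickOne(seq_along(ss), ruleId)
        ss[[i]] <- mod(ss[[i]], "contentDiagnosis", "X999")
      },
      "R-TMPL-REQ" = {
        i <- .pickOne(which(vapply(es, function(e)
          identical(e@eventKind, "disease_diagnosis"), logical(1))), ruleId)
        es[[i]] <- mod(es[[i]], "extraAttributes", list())
      },
      "R-TMPL-LINK" = {
        i <- .pickOne(which(vapply(es, function(e)
          identical(e@eventKind, "sampling") && !is.na(e@donorRef),
          logical(1))), ruleId)
        es[[i]] <- mod(es[[i]], "sampleRef", NA_character_)
      },
      "R-LIST-DUP" = {
        i <- .pickOne(which(vapply(ss, function(s)
          length(s@useRestrictions) > 0, logical(1))), ruleId)
        ur <- ss[[i]]@useRestrictions
        ss[[i]] <- mod(ss[[i]], "useRestrictions", c(ur, ur[1]))
      },
      "R-CHRONO" = {
        i <- .pickOne(Filter(function(i) {
          did <- .eventDonorId(es[[i]], rs)
          !is.na(did) && !is.null(rs@donors[[did]]@birthDate)
        }, dateEvents), ruleId)
        did <- .eventDonorId(es[[i]], rs)
        by <- rs@donors[[did]]@birthDate@year
        es[[i]] <- mod(es[[i]], "eventDatetime",
                       PartialTimestamp(by - 5L))
      },
      "R-EVENT-KIND" = {
        i <- .pickOne(seq_along(es), ruleId)
        es[[i]] <- mod(es[[i]], "eventKind", "alien_kind")
      },
      "R-DEATH-UNIQUE" = {
        i <- .pickOne(which(vapply(es, function(e)
          identical(e@eventKind, "death"), logical(1))), ruleId)
        e <- es[[i]]
        e2 <- mod(e, "eventId", .randHex())
        es[[length(es) + 1L]] <- e2
      },
      stop("no mutation implemented for rule '", ruleId, "'"))
    makeRecordSet(donors = ds, samples = ss, events = es,
                  collections = rs@collections, biobanks = rs@biobanks)
  })
}

#' Declared entailments of a rule's knockout
#'
#' Some violations logically entail findings of a second rule (removing
#' both references from a templated event breaks the generic linkage rule
#' and the template's linkage rule at once).  The mutation suite treats
#' entailed findings as expected.
#'
#' @param ruleId a registered rule id.
#' @return character vector of entailed rule ids (possibly empty).
#' @export
ruleEntailments <- function(ruleId) {
  switch(ruleId,
    "R-EVENT-LINK" = "R-TMPL-LINK",
    character())
}
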