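# S4 classes for the MIABIS individual-level data model.
#
# Validity methods check structure only (slot types, lengths, the
# no-precision-gap invariant of timestamps).  Conformance to the attribute
# tables (required attributes, vocabularies, conditional rules) is checked by
# validateRecordSet(), never at construction, so that non-conformant record
# sets can be loaded, reported on and repaired.

# ---------------------------------------------------------------------------
# PartialTimestamp

#' Reduced-precision ISO 8601 timestamp
#'
#' MIABIS date attributes (birth date, sample creation, event date) are ISO
#' 8601 values that may be partial, e.g. `"1975"`, `"2010-05"` or a full
#' `"yyyy-mm-ddThh:mm:ss"`.  A `PartialTimestamp` stores the calendar
#' components that are present; absent components are `NA`.  Precision has no
#' gaps: a day requires a month, a time-of-day requires a day, and a
#' time-of-day is always complete to seconds.
#'
#' @slot year,month,day,hour,minute,second integer scalars; `NA` where the
#'   component is absent (`year` never `NA`).
#' @seealso [parsePartialTimestamp()], [formatPartialTimestamp()],
#'   [ptPrecision()]
#' @export
setClass("PartialTimestamp",
  representation(year = "integer", month = "integer", day = "integer",
                 hour = "integer", minute = "integer", second = "integer"))

.daysInMonth <- function(year, month) {
  n <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[month]
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
  if (month == 2L && leap) 29L else n
}

setValidity("PartialTimestamp", function(object) {
  f <- function(s) slot(object, s)
  for (s in c("year", "month", "day", "hour", "minute", "second"))
    if (length(f(s)) != 1L) return(sprintf("slot '%s' must be length 1", s))
  if (is.na(object@year)) return("year must be present")
  if (!is.na(object@day) && is.na(object@month))
    return("day present without month (gapped precision)")
  tod <- c(object@hour, object@minute, object@second)
  if (any(!is.na(tod))) {
    if (any(is.na(tod)))
      return("time-of-day must be complete to seconds")
    if (is.na(object@day))
      return("time present without day (gapped precision)")
  }
  if (!is.na(object@month) && (object@month < 1L || object@month > 12L))
    return(sprintf("impossible month %d", object@month))
  if (!is.na(object@day) &&
      (object@day < 1L || object@day > .daysInMonth(object@year, object@month)))
    return(sprintf("impossible day %d for %04d-%02d",
                   object@day, object@year, object@month))
  if (!is.na(object@hour) &&
      (object@hour > 23L || object@minute > 59L || object@second > 59L ||
       min(tod) < 0L))
    return("impossible time of day")
  TRUE
})

setClassUnion("PartialTimestampOrNULL", c("PartialTimestamp", "NULL"))
setClassUnion("characterOrNULL", c("character", "NULL"))

# ---------------------------------------------------------------------------
# AnatomicalSite

#' Structured anatomical-site description of a sample
#'
#' Carries MIABIS-SAMPLE-05..09: the ontology used to code the anatomical
#' source (e.g. ICD-O-3 topography), its version, the code, the ontology
#' description, and a free-text fallback for unknown or insufficient
#' information.  The attribute tables require ontology and ontology version
#' whenever any ontology information (version/code/description) is provided;
#' that pairing rule is checked by the validator, not here.
#'
#' @slot ontology,ontologyVersion,code,description,freeText character
#'   scalars, `NA` where absent.
#' @export
setClass("AnatomicalSite",
  representation(ontology = "character", ontologyVersion = "character",
                 code = "character", description = "character",
                 freeText = "character"))

setValidity("AnatomicalSite", function(object) {
  for (s in slotNames(object))
    if (length(slot(object, s)) != 1L)
      return(sprintf("slot '%s' must be length 1", s))
  TRUE
})

setClassUnion("AnatomicalSiteOrNULL", c("AnatomicalSite", "NULL"))

# ---------------------------------------------------------------------------
# Records

#' Sample donor record (MIABIS-SAMPLEDONOR-01..04)
#'
#' An individual who is the source of biological material or of a digital
#' representation of a biological entity.  `dataCategories` is multi-valued;
#' `NULL` means the attribute was not recorded while `character(0)` means it
#' was recorded with no values — serialization preserves the distinction.
#'
#' @slot donorId character; pseudonymized donor identifier (MIABIS-SAMPLEDONOR-01).
#' @slot sex character; biological sex (MIABIS-SAMPLEDONOR-02).
#' @slot dataCategories character vector or `NULL` (MIABIS-SAMPLEDONOR-03).
#' @slot birthDate [PartialTimestamp-class] or `NULL` (MIABIS-SAMPLEDONOR-04);
#'   may be partial (e.g. birth year only), but must be present when a
#'   date-encoded event is linked to the donor.
#' @export
setClass("SampleDonor",
  representation(donorId = "character", sex = "character",
                 dataCategories = "characterOrNULL",
                 birthDate = "PartialTimestampOrNULL"))

#' Sample record (MIABIS-SAMPLE-01..11)
#'
#' A portion of biological material collected from a donor (or a digital
#' representation of one), described by its current storage status.
#' Pre-analytical processing history is out of the model's scope.
#'
#' @slot sampleId character; pseudonymized sample identifier, often the
#'   barcode (MIABIS-SAMPLE-01).
#' @slot detailedSampleType character; SPREC-v3-derived sample type
#'   (MIABIS-SAMPLE-02).
#' @slot storageTemperature character or `NA`; SPREC-v3-derived long-term
#'   storage temperature (MIABIS-SAMPLE-03).
#' @slot creationDatetime [PartialTimestamp-class] or `NULL` (MIABIS-SAMPLE-04).
#' @slot anatomicalSite [AnatomicalSite-class] or `NULL` (MIABIS-SAMPLE-05..09).
#' @slot contentDiagnosis character vector or `NULL` (MIABIS-SAMPLE-10);
#'   each value is `"Healthy"`, `"Unknown"`, `"Not applicable"` or an
#'   ICD-10 code.
#' @slot useRestrictions character vector or `NULL` (MIABIS-SAMPLE-11).
#' @slot donorRef character or `NA`; donorId of the source donor.
#' @slot collectionRef character or `NA`; id of the containing collection.
#' @export
setClass("Sample",
  representation(sampleId = "character", detailedSampleType = "character",
                 storageTemperature = "character",
                 creationDatetime = "PartialTimestampOrNULL",
                 anatomicalSite = "AnatomicalSiteOrNULL",
                 contentDiagnosis = "characterOrNULL",
                 useRestrictions = "characterOrNULL",
                 donorRef = "character", collectionRef = "character"))

#' Event record (MIABIS-EVENT-01..04 plus kind-specific attributes)
#'
#' Something that happens at a given place and time, related to a sample
#' and/or a sample donor.  The time link is encoded either as an event date
#' (`eventDatetime`) or as an age at event with its unit — never both.
#' `eventKind` tags the specialization (e.g. `"sampling"`,
#' `"disease_diagnosis"`, `"death"`, `"generic"`); kind-specific attributes
#' live in the open `extraAttributes` map and are validated against the
#' registered [EventKindTemplate][registerEventKind()] for the kind.
#'
#' @slot eventId character; random pseudonymized identifier (MIABIS-EVENT-01).
#' @slot eventDatetime [PartialTimestamp-class] or `NULL` (MIABIS-EVENT-02).
#' @slot ageAtEvent numeric or `NA`; decimal age, stored to 4 decimal places
#'   (MIABIS-EVENT-03).
#' @slot ageUnit character or `NA` (MIABIS-EVENT-04).
#' @slot eventKind character; specialization tag.
#' @slot extraAttributes named list of kind-specific values.
#' @slot donorRef,sampleRef character or `NA`; at least one must resolve.
#' @export
setClass("Event",
  representation(eventId = "character",
                 eventDatetime = "PartialTimestampOrNULL",
                 ageAtEvent = "numeric", ageUnit = "character",
                 eventKind = "character", extraAttributes = "list",
                 donorRef = "character", sampleRef = "character"))

#' Linkage stubs for the MIABIS Core biobank and sample-collection components
#'
#' Only the identifiers needed to link samples into collections and
#' collections into biobanks are modeled; the full MIABIS Core 2.0 attribute
#' sets are out of scope.
#'
#' @slot id character; pseudonymized identifier.
#' @slot name character or `NA`.
#' @aliases SampleCollectionStub-class
#' @export
setClass("BiobankStub",
  representation(id = "character", name = "character"))

#' @slot biobankRef character or `NA`; id of the parent biobank
#'   (`SampleCollectionStub` only).
#' @rdname BiobankStub-class
#' @export
setClass("SampleCollectionStub",
  representation(id = "character", name = "character",
                 biobankRef = "character"))

.scalarSlotsOk <- function(object, slots) {
  for (s in slots) {
    v <- slot(object, s)
    if (!is.null(v) && length(v) != 1L)
      return(sprintf("slot '%s' must be length 1", s))
  }
  TRUE
}

setValidity("SampleDonor", function(object)
  .scalarSlotsOk(object, c("donorId", "sex")))
setValidity("Sample", function(object)
  .scalarSlotsOk(object, c("sampleId", "detailedSampleType",
                           "storageTemperature", "donorRef", "collectionRef")))
setValidity("Event", function(object) {
  ok <- .scalarSlotsOk(object, c("eventId", "ageAtEvent", "ageUnit",
                                 "eventKind", "donorRef", "sampleRef"))
  if (!isTRUE(ok)) return(ok)
  x <- object@extraAttributes
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x)))))
    return("extraAttributes must be a fully named list")
  TRUE
})
setValidity("BiobankStub", function(object)
  .scalarSlotsOk(object, c("id", "name")))
setValidity("SampleCollectionStub", function(object)
  .scalarSlotsOk(object, c("id", "name", "biobankRef")))

# ---------------------------------------------------------------------------
# RecordSet

#' A linked set of MIABIS records
#'
#' The unit of validation, serialization and querying: lists of biobank and
#' collection stubs, donors, samples and events, each keyed (named) by
#' record ID and sorted bytewise by ID so that equal sets have identical
#' structure.  Constructed with [makeRecordSet()], which enforces ID
#' uniqueness but deliberately performs no constraint validation.
#'
#' @slot biobanks,collections,donors,samples,events named lists of the
#'   corresponding record classes.
#' @seealso [makeRecordSet()], [validateRecordSet()], [resolveReferences()]
#' @export
setClass("RecordSet",
  representation(biobanks = "list", collections = "list", donors = "list",
                 samples = "list", events = "list"))

setValidity("RecordSet", function(object) {
  chk <- function(slotName, cls) {
    x <- slot(object, slotName)
    if (length(x) && is.null(names(x)))
      return(sprintf("'%s' must be keyed by record ID", slotName))
    if (!all(vapply(x, is, logical(1), class2 = cls)))
      return(sprintf("'%s' must contain %s objects", slotName, cls))
    TRUE
  }
  for (p in list(c("biobanks", "BiobankStub"),
                 c("collections", "SampleCollectionStub"),
                 c("donors", "SampleDonor"),
                 c("samples", "Sample"),
                 c("events", "Event"))) {
    ok <- chk(p[1], p[2])
    if (!isTRUE(ok)) return(ok)
  }
  TRUE
})

# ---------------------------------------------------------------------------
# Profile

#' Use-case profile over the generic MIABIS model
#'
#' A declarative set of restrictions layered on the generic data model for a
#' specific use-case (e.g. a sample-locator deployment).  A profile may only
#' tighten: raise a linkage cardinality from 0..n to 1..n, promote an
#' optional attribute to required, or restrict an enumerated attribute to a
#' subset of its printed values (fixing the age unit to years, say).  A
#' restriction that would relax the generic model is rejected at load time.
#'
#' @slot name,description character scalars.
#' @slot cardinality named list mapping linkage edges
#'   (`"sample.donor"`, `"sample.collection"`, `"collection.biobank"`,
#'   `"event.donor"`, `"event.sample"`) to a minimum cardinality of `1`.
#' @slot required character vector of MIABIS attribute codes promoted to
#'   required.
#' @slot values named list mapping MIABIS codes to the restricted subset of
#'   allowed values.
#' @slot units named list; currently only `"MIABIS-EVENT-04"`, restricting
#'   the age unit.
#' @seealso [loadProfile()], [validateAgainstProfile()], [mergeProfiles()]
#' @export
setClass("MiabisProfile",
  representation(name = "character", description = "character",
                 cardinality = "list", required = "character",
                 values = "list", units = "list"))
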