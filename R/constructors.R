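# User-facing record constructors.  These coerce types and accept ISO 8601
# strings for date slots, but do NOT check conformance to the attribute
# tables — that is validateRecordSet()'s job.

.asPt <- function(x) {
  if (is.null(x)) return(NULL)
  if (is(x, "PartialTimestamp")) return(x)
  if (is.character(x) && length(x) == 1L && !is.na(x))
    return(parsePartialTimestamp(x))
  stop("expected a PartialTimestamp, an ISO 8601 string, or NULL")
}

.asChr1 <- function(x) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) return(NA_character_)
  as.character(x)
}

# multi-valued attributes are value sets: store them canonically in the
# printed-value order (unknown values last, bytewise) so serialization,
# including the indicator-column tabulation, is order-independent.
# Duplicates are kept so the validator can flag them.
.canonList <- function(x, vocab) {
  if (is.null(x)) return(NULL)
  x <- as.character(x)
  m <- match(x, vocab)
  known <- !is.na(m)
  c(x[known][order(m[known])], sort(x[!known], method = "radix"))
}

#' @describeIn SampleDonor-class constructor; `birthDate` may be an ISO 8601
#'   string, a [PartialTimestamp-class], or `NULL`.
#' @param donorId,sex,dataCategories,birthDate see the slot descriptions.
#' @export
SampleDonor <- function(donorId, sex = NA, dataCategories = NULL,
                        birthDate = NULL) {
  new("SampleDonor", donorId = .asChr1(donorId), sex = .asChr1(sex),
      dataCategories = .canonList(dataCategories, .VOCAB$data_categories),
      birthDate = .asPt(birthDate))
}

#' @describeIn AnatomicalSite-class constructor.
#' @param ontology,ontologyVersion,code,description,freeText see the slot
#'   descriptions.
#' @export
AnatomicalSite <- function(ontology = NA, ontologyVersion = NA, code = NA,
                           description = NA, freeText = NA) {
  new("AnatomicalSite", ontology = .asChr1(ontology),
      ontologyVersion = .asChr1(ontologyVersion), code = .asChr1(code),
      description = .asChr1(description), freeText = .asChr1(freeText))
}

#' @describeIn Sample-class constructor; `creationDatetime` may be an ISO
#'   8601 string.
#' @param sampleId,detailedSampleType,storageTemperature,creationDatetime
#'   see the slot descriptions.
#' @param anatomicalSite,contentDiagnosis,useRestrictions,donorRef,collectionRef
#'   see the slot descriptions.
#' @export
Sample <- function(sampleId, detailedSampleType = NA,
                   storageTemperature = NA, creationDatetime = NULL,
                   anatomicalSite = NULL, contentDiagnosis = NULL,
                   useRestrictions = NULL, donorRef = NA,
                   collectionRef = NA) {
  new("Sample", sampleId = .asChr1(sampleId),
      detailedSampleType = .asChr1(detailedSampleType),
      storageTemperature = .asChr1(storageTemperature),
      creationDatetime = .asPt(creationDatetime),
      anatomicalSite = anatomicalSite,
      contentDiagnosis = .canonList(contentDiagnosis,
                                    .VOCAB$content_diagnosis_keywords),
      useRestrictions = .canonList(useRestrictions,
                                   .VOCAB$use_restrictions),
      donorRef = .asChr1(donorRef), collectionRef = .asChr1(collectionRef))
}

#' @describeIn Event-class constructor; `eventDatetime` may be an ISO 8601
#'   string.  `ageAtEvent` is stored as a decimal rounded to 4 places
#'   (gestational-week ages have sub-integer meaning).
#' @param eventId,eventDatetime,ageAtEvent,ageUnit,eventKind,extraAttributes
#'   see the slot descriptions.
#' @param donorRef,sampleRef see the slot descriptions.
#' @export
Event <- function(eventId, eventDatetime = NULL, ageAtEvent = NA,
                  ageUnit = NA, eventKind = "generic",
                  extraAttributes = list(), donorRef = NA, sampleRef = NA) {
  if (length(extraAttributes))  # canonical key order for byte-stable output
    extraAttributes <- extraAttributes[order(names(extraAttributes),
                                             method = "radix")]
  new("Event", eventId = .asChr1(eventId),
      eventDatetime = .asPt(eventDatetime),
      ageAtEvent = round(as.numeric(ageAtEvent), 4L),
      ageUnit = .asChr1(ageUnit), eventKind = .asChr1(eventKind),
      extraAttributes = extraAttributes,
      donorRef = .asChr1(donorRef), sampleRef = .asChr1(sampleRef))
}

#' @describeIn BiobankStub-class constructor.
#' @param id,name,biobankRef see the slot descriptions.
#' @export
BiobankStub <- function(id, name = NA) {
  new("BiobankStub", id = .asChr1(id), name = .asChr1(name))
}

#' @describeIn BiobankStub-class constructor for the collection stub.
#' @export
SampleCollectionStub <- function(id, name = NA, biobankRef = NA) {
  new("SampleCollectionStub", id = .asChr1(id), name = .asChr1(name),
      biobankRef = .asChr1(biobankRef))
}

setMethod("show", "SampleDonor", function(object) {
  cat("SampleDonor ", object@donorId, " (sex: ", object@sex,
      if (!is.null(object@birthDate))
        paste0(", born ", formatPartialTimestamp(object@birthDate)),
      ")\n", sep = "")
})

setMethod("show", "Sample", function(object) {
  cat("Sample ", object@sampleId, " [", object@detailedSampleType, "]",
      if (!is.na(object@donorRef)) paste0(" donor=", object@donorRef),
      "\n", sep = "")
})

setMethod("show", "Event", function(object) {
  enc <- if (!is.null(object@eventDatetime))
    paste0("at ", formatPartialTimestamp(object@eventDatetime))
  else if (!is.na(object@ageAtEvent))
    paste0("age ", object@ageAtEvent, " ", object@ageUnit)
  else "no time encoding"
  cat("Event ", object@eventId, " <", object@eventKind, "> ", enc, "\n",
      sep = "")
})
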