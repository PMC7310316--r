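# Canonical JSON serialization.
#
# One document per RecordSet; attribute keys are the printed MIABIS codes.
# The writer is canonical — keys sorted, arrays ordered bytewise by record
# ID — so structurally equal RecordSets produce byte-identical documents.
# The recorded/not-recorded distinction for multi-valued attributes is
# preserved: an empty array means "recorded with no values", an absent key
# means "not recorded".  Validity is never required for serialization, so
# non-conformant sets can be written out, repaired and reloaded.

.dropNull <- function(x) x[!vapply(x, is.null, logical(1))]

.sortKeys <- function(x) x[order(names(x), method = "radix")]

.jsonScalar <- function(x) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) NULL else x
}

.donorToList <- function(d) {
  .sortKeys(.dropNull(list(
    "MIABIS-SAMPLEDONOR-01" = .jsonScalar(d@donorId),
    "MIABIS-SAMPLEDONOR-02" = .jsonScalar(d@sex),
    "MIABIS-SAMPLEDONOR-03" = if (!is.null(d@dataCategories)) I(d@dataCategories),
    "MIABIS-SAMPLEDONOR-04" = if (!is.null(d@birthDate))
      formatPartialTimestamp(d@birthDate))))
}

.sampleToList <- function(s) {
  a <- s@anatomicalSite
  .sortKeys(.dropNull(list(
    "MIABIS-SAMPLE-01" = .jsonScalar(s@sampleId),
    "MIABIS-SAMPLE-02" = .jsonScalar(s@detailedSampleType),
    "MIABIS-SAMPLE-03" = .jsonScalar(s@storageTemperature),
    "MIABIS-SAMPLE-04" = if (!is.null(s@creationDatetime))
      formatPartialTimestamp(s@creationDatetime),
    "MIABIS-SAMPLE-05" = if (!is.null(a)) .jsonScalar(a@ontology),
    "MIABIS-SAMPLE-06" = if (!is.null(a)) .jsonScalar(a@ontologyVersion),
    "MIABIS-SAMPLE-07" = if (!is.null(a)) .jsonScalar(a@code),
    "MIABIS-SAMPLE-08" = if (!is.null(a)) .jsonScalar(a@description),
    "MIABIS-SAMPLE-09" = if (!is.null(a)) .jsonScalar(a@freeText),
    "MIABIS-SAMPLE-10" = if (!is.null(s@contentDiagnosis)) I(s@contentDiagnosis),
    "MIABIS-SAMPLE-11" = if (!is.null(s@useRestrictions)) I(s@useRestrictions),
    "collectionRef" = .jsonScalar(s@collectionRef),
    "donorRef" = .jsonScalar(s@donorRef))))
}

.eventToList <- function(e) {
  .sortKeys(.dropNull(list(
    "MIABIS-EVENT-01" = .jsonScalar(e@eventId),
    "MIABIS-EVENT-02" = if (!is.null(e@eventDatetime))
      formatPartialTimestamp(e@eventDatetime),
    "MIABIS-EVENT-03" = .jsonScalar(e@ageAtEvent),
    "MIABIS-EVENT-04" = .jsonScalar(e@ageUnit),
    "donorRef" = .jsonScalar(e@donorRef),
    "eventKind" = .jsonScalar(e@eventKind),
    "extraAttributes" = if (length(e@extraAttributes))
      .sortKeys(e@extraAttributes),
    "sampleRef" = .jsonScalar(e@sampleRef))))
}

.collectionToList <- function(cl) {
  .sortKeys(.dropNull(list(id = .jsonScalar(cl@id),
                           name = .jsonScalar(cl@name),
                           biobankRef = .jsonScalar(cl@biobankRef))))
}

.biobankToList <- function(b) {
  .sortKeys(.dropNull(list(id = .jsonScalar(b@id),
                           name = .jsonScalar(b@name))))
}

#' Write a RecordSet as a canonical JSON document
#'
#' @param rs a [RecordSet-class].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when `path` is given).
#' @seealso [readRecordSetJson()]
#' @export
writeRecordSetJson <- function(rs, path = NULL) {
  stopifnot(is(rs, "RecordSet"))
  doc <- list(
    biobanks = unname(lapply(rs@biobanks, .biobankToList)),
    collections = unname(lapply(rs@collections, .collectionToList)),
    donors = unname(lapply(rs@donors, .donorToList)),
    events = unname(lapply(rs@events, .eventToList)),
    samples = unname(lapply(rs@samples, .sampleToList)))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                          digits = NA, null = "null")
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path, useBytes = TRUE)
  invisible(as.character(txt))
}

.jsonChr1 <- function(x, path) {
  if (is.null(x)) return(NA_character_)
  if (!is.character(x) && !is.numeric(x) || length(x) != 1L)
    stop("malformed scalar at ", path)
  as.character(x)
}

.jsonChrVec <- function(x, path) {
  if (is.null(x)) return(NULL)
  if (!is.list(x) && !is.character(x)) stop("malformed array at ", path)
  as.character(unlist(x, use.names = FALSE) %||% character())
}

.jsonPt <- function(x, path) {
  if (is.null(x)) return(NULL)
  tryCatch(parsePartialTimestamp(.jsonChr1(x, path)),
           error = function(e) stop("at ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
}

.checkKeys <- function(rec, known, path) {
  extra <- setdiff(names(rec), known)
  if (length(extra))
    stop("unknown attribute key(s) at ", path, ": ",
         paste(extra, collapse = ", "))
}

#' Read a RecordSet from a canonical JSON document
#'
#' @param x a file path or a JSON string.
#' @return a [RecordSet-class]; `readRecordSetJson(writeRecordSetJson(rs))`
#'   is structurally identical to `rs`.
#' @export
readRecordSetJson <- function(x) {
  txt <- if (length(x) == 1L && file.exists(x))
    paste(readLines(x, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  else paste(x, collapse = "\n")
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  known <- c("biobanks", "collections", "donors", "samples", "events")
  extra <- setdiff(names(doc), known)
  if (length(extra))
    stop("unknown component(s) at $: ", paste(extra, collapse = ", "))

  donors <- lapply(seq_along(doc$donors), function(i) {
    rec <- doc$donors[[i]]
    p <- sprintf("$.donors[%d]", i)
    .checkKeys(rec, sprintf("MIABIS-SAMPLEDONOR-%02d", 1:4), p)
    SampleDonor(
      donorId = .jsonChr1(rec[["MIABIS-SAMPLEDONOR-01"]], p),
      sex = .jsonChr1(rec[["MIABIS-SAMPLEDONOR-02"]], p),
      dataCategories = .jsonChrVec(rec[["MIABIS-SAMPLEDONOR-03"]], p),
      birthDate = .jsonPt(rec[["MIABIS-SAMPLEDONOR-04"]],
                          paste0(p, ".MIABIS-SAMPLEDONOR-04")))
  })

  samples <- lapply(seq_along(doc$samples), function(i) {
    rec <- doc$samples[[i]]
    p <- sprintf("$.samples[%d]", i)
    .checkKeys(rec, c(sprintf("MIABIS-SAMPLE-%02d", 1:11),
                      "donorRef", "collectionRef"), p)
    anat <- NULL
    av <- lapply(sprintf("MIABIS-SAMPLE-%02d", 5:9),
                 function(k) .jsonChr1(rec[[k]], p))
    if (any(!is.na(unlist(av))))
      anat <- AnatomicalSite(av[[1]], av[[2]], av[[3]], av[[4]], av[[5]])
    Sample(
      sampleId = .jsonChr1(rec[["MIABIS-SAMPLE-01"]], p),
      detailedSampleType = .jsonChr1(rec[["MIABIS-SAMPLE-02"]], p),
      storageTemperature = .jsonChr1(rec[["MIABIS-SAMPLE-03"]], p),
      creationDatetime = .jsonPt(rec[["MIABIS-SAMPLE-04"]],
                                 paste0(p, ".MIABIS-SAMPLE-04")),
      anatomicalSite = anat,
      contentDiagnosis = .jsonChrVec(rec[["MIABIS-SAMPLE-10"]], p),
      useRestrictions = .jsonChrVec(rec[["MIABIS-SAMPLE-11"]], p),
      donorRef = .jsonChr1(rec[["donorRef"]], p),
      collectionRef = .jsonChr1(rec[["collectionRef"]], p))
  })

  events <- lapply(seq_along(doc$events), function(i) {
    rec <- doc$events[[i]]
    p <- sprintf("$.events[%d]", i)
    .checkKeys(rec, c(sprintf("MIABIS-EVENT-%02d", 1:4), "eventKind",
                      "extraAttributes", "donorRef", "sampleRef"), p)
    age <- rec[["MIABIS-EVENT-03"]]
    if (!is.null(age) && !is.numeric(age))
      stop("malformed decimal at ", p, ".MIABIS-EVENT-03")
    Event(
      eventId = .jsonChr1(rec[["MIABIS-EVENT-01"]], p),
      eventDatetime = .jsonPt(rec[["MIABIS-EVENT-02"]],
                              paste0(p, ".MIABIS-EVENT-02")),
      ageAtEvent = if (is.null(age)) NA else age,
      ageUnit = .jsonChr1(rec[["MIABIS-EVENT-04"]], p),
      eventKind = .jsonChr1(rec[["eventKind"]], p),
      extraAttributes = rec[["extraAttributes"]] %||% list(),
      donorRef = .jsonChr1(rec[["donorRef"]], p),
      sampleRef = .jsonChr1(rec[["sampleRef"]], p))
  })

  collections <- lapply(seq_along(doc$collections), function(i) {
    rec <- doc$collections[[i]]
    p <- sprintf("$.collections[%d]", i)
    .checkKeys(rec, c("id", "name", "biobankRef"), p)
    SampleCollectionStub(.jsonChr1(rec$id, p), .jsonChr1(rec$name, p),
                         .jsonChr1(rec$biobankRef, p))
  })

  biobanks <- lapply(seq_along(doc$biobanks), function(i) {
    rec <- doc$biobanks[[i]]
    p <- sprintf("$.biobanks[%d]", i)
    .checkKeys(rec, c("id", "name"), p)
    BiobankStub(.jsonChr1(rec$id, p), .jsonChr1(rec$name, p))
  })

  makeRecordSet(donors = donors, samples = samples, events = events,
                collections = collections, biobanks = biobanks)
}
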