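# RecordSet construction, accessors and reference resolution.

.keyById <- function(records, idSlot) {
  ids <- vapply(records, function(r) slot(r, idSlot), character(1))
  records <- setNames(records, ids)
  # bytewise ID order makes equal sets structurally identical and the
  # canonical JSON writer trivial
  records[order(names(records), method = "radix")]
}

.checkUniqueIds <- function(ids, component) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", component, " ID(s): ", paste(dup, collapse = ", "))
}

#' Assemble a RecordSet from individual records
#'
#' Builds the linked-record container with per-component ID indexes.  ID
#' uniqueness is enforced at construction: donor, event, collection and
#' biobank IDs must be unique within the set; a sample ID must be unique
#' within its collection when `collectionRef` is set, and unique within the
#' whole set otherwise.  No constraint validation happens here — a set that
#' violates the attribute tables can still be constructed, inspected and
#' serialized; run [validateRecordSet()] explicitly.
#'
#' @param donors,samples,events,collections,biobanks lists of the
#'   corresponding record objects (a bare record is accepted in place of a
#'   length-1 list).
#' @return a [RecordSet-class].
#' @examples
#' rs <- makeRecordSet(
#'   donors = list(SampleDonor("D1", sex = "female")),
#'   samples = list(Sample("S1", "Serum", donorRef = "D1")))
#' rs
#' @export
makeRecordSet <- function(donors = list(), samples = list(),
                          events = list(), collections = list(),
                          biobanks = list()) {
  wrap <- function(x, cls) if (is(x, cls)) list(x) else x
  donors <- wrap(donors, "SampleDonor")
  samples <- wrap(samples, "Sample")
  events <- wrap(events, "Event")
  collections <- wrap(collections, "SampleCollectionStub")
  biobanks <- wrap(biobanks, "BiobankStub")

  donors <- .keyById(donors, "donorId")
  samples <- .keyById(samples, "sampleId")
  events <- .keyById(events, "eventId")
  collections <- .keyById(collections, "id")
  biobanks <- .keyById(biobanks, "id")

  .checkUniqueIds(names(donors), "donor")
  .checkUniqueIds(names(events), "event")
  .checkUniqueIds(names(collections), "collection")
  .checkUniqueIds(names(biobanks), "biobank")
  # sample IDs: unique per collection when assigned to one, otherwise
  # unique across the whole set
  if (length(samples)) {
    ids <- names(samples)
    colls <- vapply(samples, function(s) s@collectionRef, character(1))
    for (id in unique(ids[duplicated(ids)])) {
      sc <- colls[ids == id]
      if (anyNA(sc) || anyDuplicated(sc))
        stop("duplicate sample ID '", id,
             "' within one uniqueness scope (collection/record set)")
    }
  }
  new("RecordSet", biobanks = biobanks, collections = collections,
      donors = donors, samples = samples, events = events)
}

#' @name RecordSet-accessors
#' @title Accessors for RecordSet components
#' @description `donors()`, `samples()`, `events()`, `collections()` and
#'   `biobanks()` return the named (ID-keyed) record lists of a
#'   [RecordSet-class].
#' @param x a `RecordSet`.
#' @return a named list of records.
NULL

#' @rdname RecordSet-accessors
#' @export
setGeneric("donors", function(x) standardGeneric("donors"))
#' @rdname RecordSet-accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname RecordSet-accessors
#' @export
setGeneric("events", function(x) standardGeneric("events"))
#' @rdname RecordSet-accessors
#' @export
setGeneric("collections", function(x) standardGeneric("collections"))
#' @rdname RecordSet-accessors
#' @export
setGeneric("biobanks", function(x) standardGeneric("biobanks"))

#' @rdname RecordSet-accessors
setMethod("donors", "RecordSet", function(x) x@donors)
#' @rdname RecordSet-accessors
setMethod("samples", "RecordSet", function(x) x@samples)
#' @rdname RecordSet-accessors
setMethod("events", "RecordSet", function(x) x@events)
#' @rdname RecordSet-accessors
setMethod("collections", "RecordSet", function(x) x@collections)
#' @rdname RecordSet-accessors
setMethod("biobanks", "RecordSet", function(x) x@biobanks)

setMethod("show", "RecordSet", function(object) {
  cat("MIABIS RecordSet:",
      length(object@donors), "donor(s),",
      length(object@samples), "sample(s),",
      length(object@events), "event(s),",
      length(object@collections), "collection(s),",
      length(object@biobanks), "biobank(s)\n")
})

#' Report dangling references in a RecordSet
#'
#' Walks every linkage edge of the data model (sample to donor, sample to
#' collection, collection to biobank, event to donor and to sample) and
#' reports references whose target ID does not exist.  Reports, not
#' exceptions: an empty result means every reference resolves.  An event
#' with *no* reference at all is a constraint-rule matter
#' (see [validateRecordSet()]), not a dangling reference.
#'
#' @param rs a [RecordSet-class].
#' @return a data.frame with columns `component`, `id`, `field`, `target`;
#'   zero rows when fully linked.
#' @examples
#' rs <- makeRecordSet(samples = list(Sample("S1", "Serum", donorRef = "D9")))
#' resolveReferences(rs)
#' @export
resolveReferences <- function(rs) {
  stopifnot(is(rs, "RecordSet"))
  out <- list()
  add <- function(component, id, field, target)
    out[[length(out) + 1L]] <<- data.frame(
      component = component, id = id, field = field, target = target,
      stringsAsFactors = FALSE)
  for (s in rs@samples) {
    if (!is.na(s@donorRef) && !(s@donorRef %in% names(rs@donors)))
      add("sample", s@sampleId, "donorRef", s@donorRef)
    if (!is.na(s@collectionRef) &&
        !(s@collectionRef %in% names(rs@collections)))
      add("sample", s@sampleId, "collectionRef", s@collectionRef)
  }
  for (e in rs@events) {
    if (!is.na(e@donorRef) && !(e@donorRef %in% names(rs@donors)))
      add("event", e@eventId, "donorRef", e@donorRef)
    if (!is.na(e@sampleRef) && !(e@sampleRef %in% names(rs@samples)))
      add("event", e@eventId, "sampleRef", e@sampleRef)
  }
  for (cl in rs@collections) {
    if (!is.na(cl@biobankRef) && !(cl@biobankRef %in% names(rs@biobanks)))
      add("collection", cl@id, "biobankRef", cl@biobankRef)
  }
  if (!length(out))
    return(data.frame(component = character(), id = character(),
                      field = character(), target = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# donor linked to an event, directly or via the event's sample
.eventDonorId <- function(e, rs) {
  if (!is.na(e@donorRef) && e@donorRef %in% names(rs@donors))
    return(e@donorRef)
  if (!is.na(e@sampleRef) && e@sampleRef %in% names(rs@samples)) {
    d <- rs@samples[[e@sampleRef]]@donorRef
    if (!is.na(d) && d %in% names(rs@donors)) return(d)
  }
  NA_character_
}
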