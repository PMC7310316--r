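# Minimal attribute-level mapping to FHIR-shaped documents.
#
# One Specimen-shaped document per sample and one Patient-shaped document
# per donor, driven by a declarative mapping table.  The anatomical-site
# ontology code maps to collection.bodySite.coding.code — the canonical
# MIABIS-to-FHIR correspondence — and that entry is always present in the
# default table.  Output is "FHIR-shaped" JSON validated structurally, not
# against a FHIR profile or terminology server; unmapped attributes are
# reported, never silently dropped.

.FHIR_SEX <- c(male = "male", female = "female", unknown = "unknown",
               undifferentiated = "other")

#' Default MIABIS-to-FHIR mapping table
#'
#' Covers the identifier, sex, birth-date, sample-type, body-site and
#' collected-date attributes.  Only the body-site code entry
#' (`MIABIS-SAMPLE-07` to `Specimen.collection.bodySite.coding.code`) is
#' fixed by the standard; the remaining entries are implementer-chosen
#' defaults.  Everything not in the table is reported as unmapped by
#' [toFhir()].
#'
#' @return a data.frame with columns `miabisCode`, `targetPath` and
#'   `transform` (`identity`, `code_lookup` or `date_render`).
#' @export
defaultFhirMapping <- function() {
  data.frame(
    miabisCode = c("MIABIS-SAMPLEDONOR-01", "MIABIS-SAMPLEDONOR-02",
                   "MIABIS-SAMPLEDONOR-04", "MIABIS-SAMPLE-01",
                   "MIABIS-SAMPLE-02", "MIABIS-SAMPLE-04",
                   "MIABIS-SAMPLE-05", "MIABIS-SAMPLE-07",
                   "MIABIS-SAMPLE-08"),
    targetPath = c("Patient.identifier.value", "Patient.gender",
                   "Patient.birthDate", "Specimen.identifier.value",
                   "Specimen.type.text",
                   "Specimen.collection.collectedDateTime",
                   "Specimen.collection.bodySite.coding.system",
                   "Specimen.collection.bodySite.coding.code",
                   "Specimen.collection.bodySite.coding.display"),
    transform = c("identity", "code_lookup", "date_render", "identity",
                  "identity", "date_render", "identity", "identity",
                  "identity"),
    stringsAsFactors = FALSE)
}

.checkMapping <- function(mapping) {
  needed <- c("miabisCode", "targetPath", "transform")
  if (!is.data.frame(mapping) || !all(needed %in% names(mapping)))
    stop("mapping must be a data.frame with columns ",
         paste(needed, collapse = ", "))
  bad <- setdiff(mapping$miabisCode, .ATTRIBUTES$code)
  if (length(bad))
    stop("mapping references unknown MIABIS code(s): ",
         paste(bad, collapse = ", "))
  if (any(!nzchar(mapping$targetPath)))
    stop("mapping target paths must be non-empty")
  if (anyDuplicated(mapping$targetPath))
    stop("mapping path conflict: two codes map to the same path: ",
         paste(unique(mapping$targetPath[duplicated(mapping$targetPath)]),
               collapse = ", "))
  if (!"Specimen.collection.bodySite.coding.code" %in%
        mapping$targetPath[mapping$miabisCode == "MIABIS-SAMPLE-07"])
    stop("mapping must retain MIABIS-SAMPLE-07 -> ",
         "Specimen.collection.bodySite.coding.code")
  mapping
}

# assign a value at a dotted path (first element is the resource type)
.setPath <- function(doc, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]][-1]
  rec <- function(node, keys) {
    if (length(keys) == 1L) { node[[keys]] <- value; return(node) }
    node[[keys[1]]] <- rec(node[[keys[1]]] %||% list(), keys[-1])
    node
  }
  rec(doc, keys)
}

.applyTransform <- function(transform, value) {
  switch(transform,
    identity = value,
    code_lookup = if (value %in% names(.FHIR_SEX))
      unname(.FHIR_SEX[value]) else value,
    date_render = if (is(value, "PartialTimestamp"))
      formatPartialTimestamp(value) else value,
    value)
}

#' Emit FHIR-shaped documents from a RecordSet
#'
#' @param rs a [RecordSet-class].
#' @param mapping a mapping table, by default [defaultFhirMapping()].
#'   Checked before use: unknown codes, empty paths and path conflicts are
#'   errors.
#' @return a list with `specimens` (one Specimen-shaped nested list per
#'   sample, with a `subject` reference to the donor), `patients` (one
#'   Patient-shaped list per donor) and `coverage` — a data.frame
#'   partitioning every MIABIS attribute code into mapped and unmapped.
#' @examples
#' rs <- makeRecordSet(samples = list(Sample("S1", "Serum",
#'   anatomicalSite = AnatomicalSite("ICD-O-3", "3.2", "C50.9"))))
#' toFhir(rs)$specimens[[1]]$collection$bodySite$coding$code
#' @export
toFhir <- function(rs, mapping = defaultFhirMapping()) {
  stopifnot(is(rs, "RecordSet"))
  mapping <- .checkMapping(mapping)

  rawValue <- function(code, r) {
    switch(code,
      "MIABIS-SAMPLEDONOR-01" = .jsonScalar(r@donorId),
      "MIABIS-SAMPLEDONOR-02" = .jsonScalar(r@sex),
      "MIABIS-SAMPLEDONOR-04" = r@birthDate,
      "MIABIS-SAMPLE-01" = .jsonScalar(r@sampleId),
      "MIABIS-SAMPLE-02" = .jsonScalar(r@detailedSampleType),
      "MIABIS-SAMPLE-03" = .jsonScalar(r@storageTemperature),
      "MIABIS-SAMPLE-04" = r@creationDatetime,
      "MIABIS-SAMPLE-05" = if (!is.null(r@anatomicalSite))
        .jsonScalar(r@anatomicalSite@ontology),
      "MIABIS-SAMPLE-06" = if (!is.null(r@anatomicalSite))
        .jsonScalar(r@anatomicalSite@ontologyVersion),
      "MIABIS-SAMPLE-07" = if (!is.null(r@anatomicalSite))
        .jsonScalar(r@anatomicalSite@code),
      "MIABIS-SAMPLE-08" = if (!is.null(r@anatomicalSite))
        .jsonScalar(r@anatomicalSite@description),
      "MIABIS-SAMPLE-09" = if (!is.null(r@anatomicalSite))
        .jsonScalar(r@anatomicalSite@freeText),
      NULL)
  }

  buildDoc <- function(resourceType, record) {
    doc <- list(resourceType = resourceType)
    rows <- mapping[startsWith(mapping$targetPath,
                               paste0(resourceType, ".")), , drop = FALSE]
    for (k in seq_len(nrow(rows))) {
      v <- rawValue(rows$miabisCode[k], record)
      if (is.null(v)) next
      doc <- .setPath(doc, rows$targetPath[k],
                      .applyTransform(rows$transform[k], v))
    }
    doc
  }

  specimens <- unname(lapply(rs@samples, function(s) {
    doc <- buildDoc("Specimen", s)
    if (!is.na(s@donorRef))
      doc$subject <- list(reference = paste0("Patient/", s@donorRef))
    doc
  }))
  patients <- unname(lapply(rs@donors, function(d) buildDoc("Patient", d)))

  coverage <- data.frame(
    code = .ATTRIBUTES$code,
    mapped = .ATTRIBUTES$code %in% mapping$miabisCode,
    targetPath = mapping$targetPath[match(.ATTRIBUTES$code,
                                          mapping$miabisCode)],
    stringsAsFactors = FALSE)
  if (!length(rs@samples) && !length(rs@donors))
    coverage <- coverage[0, , drop = FALSE]

  list(specimens = specimens, patients = patients, coverage = coverage)
}
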