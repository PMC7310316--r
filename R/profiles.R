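# Use-case profiles: declarative, tightening-only restrictions over the
# generic model, applied as an extra validation layer on top of the generic
# rules.  Profile findings carry rule ids prefixed "P-" so the generic and
# profile layers are distinguishable in reports.

.PROFILE_EDGES <- c("sample.donor", "sample.collection", "collection.biobank",
                    "event.donor", "event.sample")

# attribute codes that are already required in the generic model
.GENERIC_REQUIRED <- c("MIABIS-SAMPLEDONOR-01", "MIABIS-SAMPLEDONOR-02",
                       "MIABIS-SAMPLE-01", "MIABIS-SAMPLE-02",
                       "MIABIS-EVENT-01")

#' Load and verify a use-case profile
#'
#' Accepts a YAML or JSON file path, or an equivalent named list, with the
#' keys `name`, `description`, `cardinality` (edge -> minimum 1), `required`
#' (MIABIS codes promoted to required), `values` (code -> allowed subset)
#' and `units` (code -> allowed units, age unit only).  The tightening
#' invariant is verified at load: every entry must reference a known
#' attribute or linkage edge and may only shrink value sets or raise minimum
#' cardinalities — a restriction that would relax the generic model (a value
#' outside the printed vocabulary, a cardinality below the generic minimum)
#' is a load error naming the offending entry.
#'
#' @param x file path or named list.
#' @return a verified [MiabisProfile-class].
#' @examples
#' p <- loadProfile(list(name = "locator",
#'                       cardinality = list(sample.donor = 1),
#'                       units = list(`MIABIS-EVENT-04` = "years")))
#' p
#' @export
loadProfile <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- if (grepl("\\.json$", x, ignore.case = TRUE))
      jsonlite::fromJSON(x, simplifyVector = FALSE)
    else yaml::read_yaml(x)
  }
  if (!is.list(x)) stop("profile must be a file path or a named list")

  card <- lapply(x$cardinality %||% list(), function(v) as.integer(v))
  for (edge in names(card)) {
    if (!edge %in% .PROFILE_EDGES)
      stop("profile cardinality: unknown linkage edge '", edge, "'")
    if (!identical(card[[edge]], 1L))
      stop("profile cardinality for '", edge, "' must be 1 (the generic ",
           "model already allows 0..n; anything else does not tighten)")
  }

  req <- as.character(x$required %||% character())
  bad <- setdiff(req, .ATTRIBUTES$code)
  if (length(bad))
    stop("profile required: unknown attribute code(s): ",
         paste(bad, collapse = ", "))

  checkValues <- function(restr, label) {
    for (code in names(restr)) {
      i <- match(code, .ATTRIBUTES$code)
      if (is.na(i))
        stop("profile ", label, ": unknown attribute code '", code, "'")
      vals <- as.character(restr[[code]])
      if (!length(vals))
        stop("profile ", label, " for '", code, "' is empty")
      if (code == "MIABIS-SAMPLE-10") {
        outside <- vals[!vals %in% .VOCAB$content_diagnosis_keywords &
                          !isIcd10Code(vals)]
      } else if (!is.na(.ATTRIBUTES$vocabulary[i])) {
        outside <- setdiff(vals, .VOCAB[[.ATTRIBUTES$vocabulary[i]]])
      } else {
        stop("profile ", label, ": '", code,
             "' has no closed vocabulary to restrict")
      }
      if (length(outside))
        stop("profile ", label, " for '", code, "' would relax the generic ",
             "model: value(s) outside the printed vocabulary: ",
             paste(outside, collapse = ", "))
      restr[[code]] <- vals
    }
    restr
  }
  vals <- checkValues(x$values %||% list(), "values")
  units <- x$units %||% list()
  if (length(units) && !all(names(units) == "MIABIS-EVENT-04"))
    stop("profile units: only MIABIS-EVENT-04 carries a unit")
  units <- checkValues(units, "units")

  new("MiabisProfile",
      name = as.character(x$name %||% "unnamed"),
      description = as.character(x$description %||% ""),
      cardinality = card, required = req, values = vals, units = units)
}

setMethod("show", "MiabisProfile", function(object) {
  cat("MiabisProfile '", object@name, "': ",
      length(object@cardinality), " cardinality override(s), ",
      length(object@required), " promoted attribute(s), ",
      length(object@values) + length(object@units),
      " value restriction(s)\n", sep = "")
})

# is attribute `code` recorded on record `r`? (list attributes: recorded
# means non-NULL, even if empty)
.attrRecorded <- function(code, r) {
  switch(code,
    "MIABIS-SAMPLEDONOR-01" = .present(r@donorId),
    "MIABIS-SAMPLEDONOR-02" = .present(r@sex),
    "MIABIS-SAMPLEDONOR-03" = !is.null(r@dataCategories),
    "MIABIS-SAMPLEDONOR-04" = !is.null(r@birthDate),
    "MIABIS-SAMPLE-01" = .present(r@sampleId),
    "MIABIS-SAMPLE-02" = .present(r@detailedSampleType),
    "MIABIS-SAMPLE-03" = .present(r@storageTemperature),
    "MIABIS-SAMPLE-04" = !is.null(r@creationDatetime),
    "MIABIS-SAMPLE-05" = !is.null(r@anatomicalSite) && .present(r@anatomicalSite@ontology),
    "MIABIS-SAMPLE-06" = !is.null(r@anatomicalSite) && .present(r@anatomicalSite@ontologyVersion),
    "MIABIS-SAMPLE-07" = !is.null(r@anatomicalSite) && .present(r@anatomicalSite@code),
    "MIABIS-SAMPLE-08" = !is.null(r@anatomicalSite) && .present(r@anatomicalSite@description),
    "MIABIS-SAMPLE-09" = !is.null(r@anatomicalSite) && .present(r@anatomicalSite@freeText),
    "MIABIS-SAMPLE-10" = !is.null(r@contentDiagnosis),
    "MIABIS-SAMPLE-11" = !is.null(r@useRestrictions),
    "MIABIS-EVENT-01" = .present(r@eventId),
    "MIABIS-EVENT-02" = !is.null(r@eventDatetime),
    "MIABIS-EVENT-03" = !is.na(r@ageAtEvent),
    "MIABIS-EVENT-04" = .present(r@ageUnit),
    stop("unknown attribute code '", code, "'"))
}

# recorded scalar/list values of attribute `code` on record `r`
.attrValues <- function(code, r) {
  v <- switch(code,
    "MIABIS-SAMPLEDONOR-02" = r@sex,
    "MIABIS-SAMPLEDONOR-03" = r@dataCategories,
    "MIABIS-SAMPLE-02" = r@detailedSampleType,
    "MIABIS-SAMPLE-03" = r@storageTemperature,
    "MIABIS-SAMPLE-10" = r@contentDiagnosis,
    "MIABIS-SAMPLE-11" = r@useRestrictions,
    "MIABIS-EVENT-04" = r@ageUnit,
    NULL)
  v[!is.na(v)]
}

.recordsOfComponent <- function(rs, component) {
  switch(component, donor = rs@donors, sample = rs@samples,
         event = rs@events)
}

#' Validate a RecordSet under a use-case profile
#'
#' Returns the union of the generic findings ([validateRecordSet()]) and the
#' profile's additional findings.  Profile rule ids are prefixed `"P-"`:
#' `P-CARD-<edge>` for a linkage edge tightened to 1..n that is unmet,
#' `P-REQ-<code>` for a promoted attribute that is missing, and
#' `P-VALUE-<code>` / `P-UNIT-<code>` for a recorded value outside the
#' profile's restricted set.  Because profiles only tighten, the generic
#' findings are always a subset of the profiled findings.
#'
#' @param rs a [RecordSet-class].
#' @param profile a [MiabisProfile-class] from [loadProfile()].
#' @param strictBirthdate passed through to [validateRecordSet()].
#' @return a findings data.frame (same shape as [validateRecordSet()]).
#' @export
validateAgainstProfile <- function(rs, profile, strictBirthdate = FALSE) {
  stopifnot(is(rs, "RecordSet"), is(profile, "MiabisProfile"))
  out <- list(validateRecordSet(rs, strictBirthdate = strictBirthdate))
  pf <- function(ruleId, component, recordId, codes, message) {
    f <- .mkFinding(ruleId, component, recordId, codes, message)
    f$severity <- "error"
    out[[length(out) + 1L]] <<- f
  }

  for (edge in names(profile@cardinality)) {
    switch(edge,
      "sample.donor" = for (s in rs@samples) {
        if (is.na(s@donorRef) || !(s@donorRef %in% names(rs@donors)))
          pf("P-CARD-sample.donor", "sample", s@sampleId, "",
             "profile requires donor information for every sample (1..n)")
      },
      "sample.collection" = for (s in rs@samples) {
        if (is.na(s@collectionRef) ||
            !(s@collectionRef %in% names(rs@collections)))
          pf("P-CARD-sample.collection", "sample", s@sampleId, "",
             "profile requires a collection for every sample (1..n)")
      },
      "collection.biobank" = for (cl in rs@collections) {
        if (is.na(cl@biobankRef) || !(cl@biobankRef %in% names(rs@biobanks)))
          pf("P-CARD-collection.biobank", "collection", cl@id, "",
             "profile requires a biobank for every collection (1..n)")
      },
      "event.donor" = for (e in rs@events) {
        if (is.na(.eventDonorId(e, rs)))
          pf("P-CARD-event.donor", "event", e@eventId, "",
             "profile requires every event to be linkable to a donor (1..n)")
      },
      "event.sample" = for (e in rs@events) {
        if (is.na(e@sampleRef) || !(e@sampleRef %in% names(rs@samples)))
          pf("P-CARD-event.sample", "event", e@eventId, "",
             "profile requires every event to reference a sample (1..n)")
      })
  }

  for (code in profile@required) {
    component <- .ATTRIBUTES$component[match(code, .ATTRIBUTES$code)]
    for (r in .recordsOfComponent(rs, component)) {
      if (!.attrRecorded(code, r))
        pf(paste0("P-REQ-", code), component, slot(r, slotNames(r)[1]),
           code, sprintf("profile promotes %s to required", code))
    }
  }

  checkRestr <- function(restr, prefix) {
    for (code in names(restr)) {
      component <- .ATTRIBUTES$component[match(code, .ATTRIBUTES$code)]
      allowed <- restr[[code]]
      for (r in .recordsOfComponent(rs, component)) {
        bad <- setdiff(.attrValues(code, r), allowed)
        if (length(bad))
          pf(paste0(prefix, code), component, slot(r, slotNames(r)[1]),
             code, sprintf("value(s) outside the profile's allowed set for %s: %s",
                           code, paste(bad, collapse = ", ")))
      }
    }
  }
  checkRestr(profile@values, "P-VALUE-")
  checkRestr(profile@units, "P-UNIT-")

  res <- do.call(rbind, c(out, list(.emptyFindings())))
  res <- res[order(res$component, res$recordId, res$ruleId, res$message,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge two use-case profiles
#'
#' The merge is the union of the two restriction sets: cardinality overrides
#' and promoted attributes are unioned, value/unit restrictions on the same
#' attribute are intersected.  Where restrictions are disjoint the merge is
#' commutative; an empty intersection (conflicting fixed values) fails at
#' merge time.
#'
#' @param a,b [MiabisProfile-class] objects.
#' @return the merged [MiabisProfile-class].
#' @export
mergeProfiles <- function(a, b) {
  stopifnot(is(a, "MiabisProfile"), is(b, "MiabisProfile"))
  mergeRestr <- function(x, y, label) {
    for (code in names(y)) {
      if (is.null(x[[code]])) x[[code]] <- y[[code]]
      else {
        common <- intersect(x[[code]], y[[code]])
        if (!length(common))
          stop("conflicting ", label, " restrictions for '", code,
               "': empty intersection")
        x[[code]] <- common
      }
    }
    x
  }
  card <- a@cardinality
  for (edge in names(b@cardinality)) card[[edge]] <- 1L
  new("MiabisProfile",
      name = paste(a@name, b@name, sep = "+"),
      description = paste(a@description, b@description, sep = " / "),
      cardinality = card,
      required = sort(union(a@required, b@required)),
      values = mergeRestr(a@values, b@values, "value"),
      units = mergeRestr(a@units, b@units, "unit"))
}
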