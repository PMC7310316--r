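# The constraint-validation engine.
#
# Every rule printed in the MIABIS attribute tables (and the required-
# attribute markings of the generic data model) is registered here with a
# stable rule id, a severity, the attribute codes involved, and the
# constraint wording it enforces.  Rules the standard does not print
# (referential integrity, chronology, list-duplicate hygiene) are marked
# "design decision" and are at most warnings unless structural (dangling
# references are errors, since nothing downstream is meaningful without
# resolvable links).

.emptyFindings <- function() {
  data.frame(ruleId = character(), severity = character(),
             component = character(), recordId = character(),
             codes = character(), message = character(),
             stringsAsFactors = FALSE)
}

.present <- function(x) length(x) == 1L && !is.na(x) && nzchar(x)

# ---------------------------------------------------------------------------
# Rule table: id, severity, MIABIS codes, description, anchor, check().
# Each check(rs, opts) returns a findings data.frame.

.mkFinding <- function(ruleId, component, recordId, codes, message) {
  data.frame(ruleId = ruleId, severity = NA_character_,
             component = component,
             recordId = ifelse(is.na(recordId), "<missing-id>", recordId),
             codes = codes, message = message, stringsAsFactors = FALSE)
}

.RULES <- list(

  list(id = "R-REF", severity = "error", codes = "",
       description = "All donor/sample/collection/biobank references resolve to an existing record.",
       anchor = "design decision",
       check = function(rs, opts) {
         dang <- resolveReferences(rs)
         if (!nrow(dang)) return(.emptyFindings())
         .mkFinding("R-REF", dang$component, dang$id, "",
                    sprintf("%s '%s' references missing record '%s'",
                            dang$field, dang$id, dang$target))
       }),

  list(id = "R-DONOR-REQ", severity = "error",
       codes = "MIABIS-SAMPLEDONOR-01;MIABIS-SAMPLEDONOR-02",
       description = "Donor ID and biological sex are required on every sample donor (cardinality 1).",
       anchor = "Sample Donor attribute table: cardinality 1 for Sample donor ID and Sex; required attributes are asterisk-marked in the generic data model",
       check = function(rs, opts) {
         out <- .emptyFindings()
         for (d in rs@donors) {
           miss <- c(if (!.present(d@donorId)) "MIABIS-SAMPLEDONOR-01",
                     if (!.present(d@sex)) "MIABIS-SAMPLEDONOR-02")
           if (length(miss))
             out <- rbind(out, .mkFinding("R-DONOR-REQ", "donor", d@donorId,
               paste(miss, collapse = ";"),
               paste("missing required attribute(s):",
                     paste(miss, collapse = ", "))))
         }
         out
       }),

  list(id = "R-SAMPLE-REQ", severity = "error",
       codes = "MIABIS-SAMPLE-01;MIABIS-SAMPLE-02",
       description = "Sample ID and detailed sample type are required on every sample (cardinality 1).",
       anchor = "Sample attribute table: cardinality 1 for Sample ID and Detailed sample type; asterisk-marked in the generic data model",
       check = function(rs, opts) {
         out <- .emptyFindings()
         for (s in rs@samples) {
           miss <- c(if (!.present(s@sampleId)) "MIABIS-SAMPLE-01",
                     if (!.present(s@detailedSampleType)) "MIABIS-SAMPLE-02")
           if (length(miss))
             out <- rbind(out, .mkFinding("R-SAMPLE-REQ", "sample",
               s@sampleId, paste(miss, collapse = ";"),
               paste("missing required attribute(s):",
                     paste(miss, collapse = ", "))))
         }
         out
       }),

  list(id = "R-EVENT-REQ", severity = "error", codes = "MIABIS-EVENT-01",
       description = "Every recorded event carries an event ID.",
       anchor = "\"Required if event is recorded\"",
       check = function(rs, opts) {
         out <- .emptyFindings()
         for (e in rs@events)
           if (!.present(e@eventId))
             out <- rbind(out, .mkFinding("R-EVENT-REQ", "event", e@eventId,
               "MIABIS-EVENT-01", "missing event ID"))
         out
       }),

  list(id = "R-ID-CODED", severity = "error",
       codes = "MIABIS-SAMPLEDONOR-01;MIABIS-SAMPLE-01;MIABIS-EVENT-01",
       description = "Identifiers are pseudonymized alphanumeric coded strings ([A-Za-z0-9._-]+).",
       anchor = "\"Pseudonymized, alphanumeric\"",
       check = function(rs, opts) {
         out <- .emptyFindings()
         add <- function(component, id, code) {
           if (.present(id) && !isCodedString(id))
             out <<- rbind(out, .mkFinding("R-ID-CODED", component, id, code,
               sprintf("identifier '%s' is not a pseudonymized alphanumeric coded string", id)))
         }
         for (d in rs@donors) add("donor", d@donorId, "MIABIS-SAMPLEDONOR-01")
         for (s in rs@samples) add("sample", s@sampleId, "MIABIS-SAMPLE-01")
         for (e in rs@events) add("event", e@eventId, "MIABIS-EVENT-01")
         for (cl in rs@collections) add("collection", cl@id, "")
         for (b in rs@biobanks) add("biobank", b@id, "")
         out
       }),

  list(id = "R-EVENT-XOR", severity = "error",
       codes = "MIABIS-EVENT-02;MIABIS-EVENT-03",
       description = "An event is time-linked by either an event date or an age at event, never both.",
       anchor = "\"Use either age at event or event date and time, not both\"",
       check = function(rs, opts) {
         out <- .emptyFindings()
         for (e in rs@events)
           if (!is.null(e@eventDatetime) && !is.na(e@ageAtEvent))
             out <- rbind(out, .mkFinding("R-EVENT-XOR", "event", e@eventId,
               "MIABIS-EVENT-02;MIABIS-EVENT-03",
               "both event date and age at event are recorded"))
         out
       }),

  list(id = "R-EVENT-AGEUNIT", severity = "error",
       codes = "MIABIS-EVENT-03;MIABIS-EVENT-04",
       description = "An age at event must carry its unit.",
       anchor = "\"When age at event is provided, age unit is required\"",
       check = function(rs, opts) {
         out <- .emptyFindings()
         for (e in rs@events)
           if (!is.na(e@ageAtEvent) && !.present(e@ageUnit))
             out <- rbind(out, .mkFinding("R-EVENT-AGEUNIT", "event",
               e@eventId, "MIABIS-EVENT-03;MIABIS-EVENT-04",
               "age at event recorded without an age unit"))
         out
       }),

  list(id = "R-DONOR-BIRTHDATE", severity = "error",
       codes = "MIABIS-SAMPLEDONOR-04;MIABIS-EVENT-02",
       description = "A donor linked (directly or via a sample) to a date-encoded event must have a birth date; otherwise a partial birth date, or none, suffices.",
       anchor = "\"Date of birth is required when Event date (MIABIS-EVENT-02) is used\"",
       check = function(rs, opts) {
         out <- .emptyFindings()
         offend <- list()
         for (e in rs@events) {
           if (is.null(e@eventDatetime)) next
           did <- .eventDonorId(e, rs)
           if (is.na(did)) next
           d <- rs@donors[[did]]
           bad <- is.null(d@birthDate)
           if (!bad && isTRUE(opts$strictBirthdate) &&
               .PRECISION_LEVELS[[ptPrecision(e@eventDatetime)]] >= 3L &&
               .PRECISION_LEVELS[[ptPrecision(d@birthDate)]] < 3L)
             bad <- TRUE
           if (bad) offend[[did]] <- c(offend[[did]], e@eventId)
         }
         for (did in names(offend))
           out <- rbind(out, .mkFinding("R-DONOR-BIRTHDATE", "donor", did,
             "MIABIS-SAMPLEDONOR-04;MIABIS-EVENT-02",
             sprintf("birth date required: date-encoded event(s) %s are linked to this donor",
                     paste(sort(offend[[did]]), collapse = ", "))))
         out
       }),

  list(id = "R-ANAT-PAIR", severity = "error",
       codes = "MIABIS-SAMPLE-05;MIABIS-SAMPLE-06",
       description = "Anatomical-site ontology and ontology version are required whenever any ontology information (version, code or description) is provided; free text alone does not trigger the requirement.",
       anchor = "\"MIABIS-SAMPLE-05 and MIABIS-SAMPLE-06 are required if any ontology information is provided\"",
       check = function(rs, opts) {
         out <- .emptyFindings()
         for (s in rs@samples) {
           a <- s@anatomicalSite
           if (is.null(a)) next
           anyInfo <- .present(a@ontology) || .present(a@ontologyVersion) ||
             .present(a@code) || .present(a@description)
           if (anyInfo && !(.present(a@ontology) && .present(a@ontologyVersion)))
             out <- rbind(out, .mkFinding("R-ANAT-PAIR", "sample",
               s@sampleId, "MIABIS-SAMPLE-05;MIABIS-SAMPLE-06",
               "anatomical-site ontology information given without ontology name and version"))
         }
         out
       }),

  list(id = "R-EVENT-LINK", severity = "error", codes = "",
       description = "Every event references a sample and/or a sample donor.",
       anchor = "\"An event is something that happens in a given place and time and is related to the sample and/or sample donor.\"",
       check = function(rs, opts) {
         out <- .emptyFindings()
         for (e in rs@events)
           if (is.na(e@donorRef) && is.na(e@sampleRef))
             out <- rbind(out, .mkFinding("R-EVENT-LINK", "event",
               e@eventId, "", "event references neither a sample nor a donor"))
         out
       }),

  list(id = "R-ENUM", severity = "error", codes = "",
       description = "Enumerated attributes only take values from their printed allowed-value lists (vocabulary closure; case variants are rejected unless canonicalizeValue() is invoked).",
       anchor = "allowed-value lists printed in the Sample Donor, Sample and Event attribute tables",
       check = function(rs, opts) {
         out <- .emptyFindings()
         add <- function(component, id, code, bad) {
           if (length(bad))
             out <<- rbind(out, .mkFinding("R-ENUM", component, id, code,
               sprintf("value(s) outside the allowed list for %s: %s",
                       code, paste(unique(bad), collapse = ", "))))
         }
         for (d in rs@donors) {
           if (.present(d@sex) && !d@sex %in% .VOCAB$sex)
             add("donor", d@donorId, "MIABIS-SAMPLEDONOR-02", d@sex)
           dc <- d@dataCategories
           add("donor", d@donorId, "MIABIS-SAMPLEDONOR-03",
               dc[!is.na(dc) & !dc %in% .VOCAB$data_categories])
         }
         for (s in rs@samples) {
           if (.present(s@detailedSampleType) &&
               !s@detailedSampleType %in% .VOCAB$detailed_sample_type)
             add("sample", s@sampleId, "MIABIS-SAMPLE-02",
                 s@detailedSampleType)
           if (.present(s@storageTemperature) &&
               !s@storageTemperature %in% .VOCAB$storage_temperature)
             add("sample", s@sampleId, "MIABIS-SAMPLE-03",
                 s@storageTemperature)
           ur <- s@useRestrictions
           add("sample", s@sampleId, "MIABIS-SAMPLE-11",
               ur[!is.na(ur) & !ur %in% .VOCAB$use_restrictions])
         }
         for (e in rs@events)
           if (.present(e@ageUnit) && !e@ageUnit %in% .VOCAB$age_unit)
             add("event", e@eventId, "MIABIS-EVENT-04", e@ageUnit)
         out
       }),

  list(id = "R-ICD10", severity = "error", codes = "MIABIS-SAMPLE-10",
       description = "Content-diagnosis entries are 'Healthy', 'Unknown', 'Not applicable' or format-valid ICD-10 codes.",
       anchor = "\"The ICD-10 diagnosis code describing content of the sample\"; allowed values Healthy, [ICD-10 code], Unknown, Not applicable",
       check = function(rs, opts) {
         out <- .emptyFindings()
         for (s in rs@samples) {
           cd <- s@contentDiagnosis
           bad <- cd[!is.na(cd) &
                       !cd %in% .VOCAB$content_diagnosis_keywords &
                       !isIcd10Code(cd)]
           if (length(bad))
             out <- rbind(out, .mkFinding("R-ICD10", "sample", s@sampleId,
               "MIABIS-SAMPLE-10",
               sprintf("content-diagnosis value(s) neither keyword nor ICD-10 format: %s",
                       paste(unique(bad), collapse = ", "))))
         }
         out
       }),

  list(id = "R-LIST-DUP", severity = "warning", codes = "",
       description = "Multi-valued attributes carry no duplicate values.",
       anchor = "design decision",
       check = function(rs, opts) {
         out <- .emptyFindings()
         add <- function(component, id, code, vals) {
           if (anyDuplicated(vals))
             out <<- rbind(out, .mkFinding("R-LIST-DUP", component, id, code,
               sprintf("duplicate values in %s", code)))
         }
         for (d in rs@donors)
           add("donor", d@donorId, "MIABIS-SAMPLEDONOR-03", d@dataCategories)
         for (s in rs@samples) {
           add("sample", s@sampleId, "MIABIS-SAMPLE-10", s@contentDiagnosis)
           add("sample", s@sampleId, "MIABIS-SAMPLE-11", s@useRestrictions)
         }
         out
       }),

  list(id = "R-CHRONO", severity = "warning",
       codes = "MIABIS-SAMPLEDONOR-04;MIABIS-SAMPLE-04;MIABIS-EVENT-02",
       description = "Event dates and sample creation dates do not precede the linked donor's birth date (compared at the coarser precision).",
       anchor = "design decision",
       check = function(rs, opts) {
         out <- .emptyFindings()
         for (e in rs@events) {
           if (is.null(e@eventDatetime)) next
           did <- .eventDonorId(e, rs)
           if (is.na(did)) next
           bd <- rs@donors[[did]]@birthDate
           if (!is.null(bd) && ptCompare(e@eventDatetime, bd) < 0L)
             out <- rbind(out, .mkFinding("R-CHRONO", "event", e@eventId,
               "MIABIS-EVENT-02;MIABIS-SAMPLEDONOR-04",
               "event date precedes the linked donor's birth date"))
         }
         for (s in rs@samples) {
           if (is.null(s@creationDatetime) || is.na(s@donorRef) ||
               !(s@donorRef %in% names(rs@donors))) next
           bd <- rs@donors[[s@donorRef]]@birthDate
           if (!is.null(bd) && ptCompare(s@creationDatetime, bd) < 0L)
             out <- rbind(out, .mkFinding("R-CHRONO", "sample", s@sampleId,
               "MIABIS-SAMPLE-04;MIABIS-SAMPLEDONOR-04",
               "sample creation date precedes the donor's birth date"))
         }
         out
       }),

  list(id = "R-EVENT-KIND", severity = "warning", codes = "",
       description = "Events of an unregistered kind are validated against the generic rules only.",
       anchor = "design decision",
       check = function(rs, opts) {
         out <- .emptyFindings()
         known <- names(eventKindRegistry())
         for (e in rs@events)
           if (.present(e@eventKind) && !e@eventKind %in% known)
             out <- rbind(out, .mkFinding("R-EVENT-KIND", "event",
               e@eventId, "",
               sprintf("event kind '%s' has no registered template", e@eventKind)))
         out
       }),

  list(id = "R-TMPL-REQ", severity = "error", codes = "",
       description = "Events satisfy the required/allowed extra attributes of their registered kind template.",
       anchor = "event-kind use-case templates (Sampling, Disease Diagnosis, Death); template rules are additive to the generic event rules",
       check = function(rs, opts) {
         out <- .emptyFindings()
         reg <- eventKindRegistry()
         for (e in rs@events) {
           t <- reg[[e@eventKind]]
           if (is.null(t)) next
           for (spec in t@extras) {
             v <- e@extraAttributes[[spec$name]]
             if (is.null(v)) {
               if (spec$required)
                 out <- rbind(out, .mkFinding("R-TMPL-REQ", "event",
                   e@eventId, "",
                   sprintf("kind '%s' requires extra attribute '%s'",
                           t@kind, spec$name)))
             } else {
               msg <- .checkExtraValue(spec, v)
               if (!is.null(msg))
                 out <- rbind(out, .mkFinding("R-TMPL-REQ", "event",
                   e@eventId, "", sprintf("kind '%s': %s", t@kind, msg)))
             }
           }
         }
         out
       }),

  list(id = "R-TMPL-LINK", severity = "error", codes = "",
       description = "Events satisfy the linkage rule of their registered kind template (e.g. a sampling event must reference its sample; a diagnosis or death event must be linkable to a donor).",
       anchor = "event-kind use-case templates (Sampling, Disease Diagnosis, Death)",
       check = function(rs, opts) {
         out <- .emptyFindings()
         reg <- eventKindRegistry()
         for (e in rs@events) {
           t <- reg[[e@eventKind]]
           if (is.null(t)) next
           bad <- switch(t@linkage,
             sample_required = is.na(e@sampleRef),
             donor_required = is.na(.eventDonorId(e, rs)),
             either = FALSE)
           if (bad)
             out <- rbind(out, .mkFinding("R-TMPL-LINK", "event",
               e@eventId, "",
               sprintf("kind '%s' requires a %s reference", t@kind,
                       sub("_required", "", t@linkage))))
         }
         out
       }),

  list(id = "R-DEATH-UNIQUE", severity = "warning", codes = "",
       description = "A donor has at most one death event.",
       anchor = "design decision",
       check = function(rs, opts) {
         out <- .emptyFindings()
         deaths <- Filter(function(e) identical(e@eventKind, "death"),
                          rs@events)
         dids <- vapply(deaths, .eventDonorId, character(1), rs = rs)
         for (did in unique(dids[!is.na(dids) & duplicated(dids)]))
           out <- rbind(out, .mkFinding("R-DEATH-UNIQUE", "donor", did, "",
             "more than one death event linked to this donor"))
         out
       })
)

names(.RULES) <- vapply(.RULES, `[[`, character(1), "id")

#' Validate a RecordSet against the generic MIABIS model
#'
#' Runs every registered constraint rule — the printed attribute-table
#' constraints as error-severity rules, plus warning-severity hygiene rules
#' — over the whole set and returns all findings without short-circuiting.
#' Dangling references are reported first (rule `R-REF`).  `validateRecordSet`
#' is a pure function of its inputs: repeated calls return the identical,
#' stably ordered finding table (by component, record ID, rule ID).
#'
#' @param rs a [RecordSet-class].
#' @param strictBirthdate logical; when `TRUE`, a day-precision (or finer)
#'   event date additionally demands a day-precision birth date on the
#'   linked donor.  Default `FALSE`: the birth date required by a
#'   date-encoded event may itself be partial.
#' @return a data.frame of findings with columns `ruleId`, `severity`
#'   (`"error"`/`"warning"`), `component`, `recordId`, `codes`
#'   (semicolon-separated MIABIS attribute codes) and `message`.  Zero rows
#'   iff the set conforms to the generic model.
#' @examples
#' e <- Event("E1", eventDatetime = "2010", ageAtEvent = 35,
#'            ageUnit = "years", donorRef = "D1")
#' rs <- makeRecordSet(donors = list(SampleDonor("D1", "male",
#'                                   birthDate = "1975")),
#'                     events = list(e))
#' validateRecordSet(rs)$ruleId
#' @export
validateRecordSet <- function(rs, strictBirthdate = FALSE) {
  stopifnot(is(rs, "RecordSet"))
  opts <- list(strictBirthdate = strictBirthdate)
  out <- lapply(.RULES, function(rule) {
    f <- rule$check(rs, opts)
    if (nrow(f)) f$severity <- rule$severity
    f
  })
  out <- do.call(rbind, c(out, list(.emptyFindings())))
  out <- out[order(out$component, out$recordId, out$ruleId, out$message,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Describe a registered validation rule
#'
#' @param ruleId a registered rule identifier (e.g. `"R-EVENT-XOR"`).
#' @return a list with `id`, `severity`, `codes` (MIABIS attribute codes
#'   involved), `description` and `anchor` — the constraint wording the rule
#'   enforces, or `"design decision"` for rules the standard does not print.
#' @examples
#' explainRule("R-EVENT-XOR")$anchor
#' @export
explainRule <- function(ruleId) {
  rule <- .RULES[[ruleId]]
  if (is.null(rule))
    stop("unknown rule id '", ruleId, "'; see listRules()")
  rule[c("id", "severity", "codes", "description", "anchor")]
}

#' @describeIn explainRule all registered rule ids.
#' @export
listRules <- function() names(.RULES)

#' Render findings for reporting
#'
#' `formatFindings()` renders one line per finding; `findingsToJson()`
#' serializes the finding table for machine consumption.
#'
#' @param findings a findings data.frame from [validateRecordSet()].
#' @return a character vector of lines, or a JSON string.
#' @export
formatFindings <- function(findings) {
  if (!nrow(findings)) return("0 findings")
  sprintf("[%s] %s %s/%s: %s", findings$severity, findings$ruleId,
          findings$component, findings$recordId, findings$message)
}

#' @rdname formatFindings
#' @export
findingsToJson <- function(findings) {
  jsonlite::toJSON(findings, dataframe = "rows", auto_unbox = TRUE,
                   pretty = TRUE)
}
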