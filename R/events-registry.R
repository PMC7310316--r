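# Event-kind templates: the generic Event component is deliberately minimal,
# and use-cases specialize it by registering kind templates whose extra
# attributes and linkage rules are enforced *in addition to* the generic
# rules (templates are additive, never subtractive).

#' Event-kind specialization template
#'
#' Describes one event kind: the kind tag, its extra attributes (each with a
#' semantic type, optional allowed-value set and a required flag), and its
#' linkage rule (whether the event must reference a sample, a donor, or
#' either).  Three built-in templates mirror the standard's use-case
#' examples: `sampling` (ties a sample's creation to a time point; a sample
#' reference is required), `disease_diagnosis` (a donor-level diagnosis with
#' a required diagnosis code in the same value space as the sample
#' content-diagnosis attribute) and `death` (a donor's terminal event with
#' an optional ICD-10 cause-of-death code; at most one per donor).
#'
#' @slot kind character tag, unique in the registry.
#' @slot extras list of extra-attribute specs: each a list with elements
#'   `name`, `type` (`"text"`, `"icd10"`, `"diagnosis_code"` or `"enum"`),
#'   `allowed` (character or `NULL`) and `required` (logical).
#' @slot linkage one of `"sample_required"`, `"donor_required"`, `"either"`.
#' @slot version template version string (built-ins are versioned so a
#'   deployment can replace them without API change).
#' @seealso [registerEventKind()], [builtinEventKinds()]
#' @export
setClass("EventKindTemplate",
  representation(kind = "character", extras = "list", linkage = "character",
                 version = "character"))

# names an extra attribute may not shadow
.GENERIC_EVENT_NAMES <- c(
  "MIABIS-EVENT-01", "MIABIS-EVENT-02", "MIABIS-EVENT-03", "MIABIS-EVENT-04",
  "Event ID", "Event date and time", "Age at event", "Age at event unit",
  "eventId", "eventDatetime", "ageAtEvent", "ageUnit")

setValidity("EventKindTemplate", function(object) {
  if (length(object@kind) != 1L || is.na(object@kind) || !nzchar(object@kind))
    return("kind must be a non-empty string")
  if (!object@linkage %in% c("sample_required", "donor_required", "either"))
    return("linkage must be sample_required, donor_required or either")
  nm <- vapply(object@extras, function(x) x$name %||% NA_character_,
               character(1))
  if (anyNA(nm) || anyDuplicated(nm))
    return("extras must have unique 'name' entries")
  bad <- intersect(nm, .GENERIC_EVENT_NAMES)
  if (length(bad))
    return(paste0("extra attribute name collides with a generic event ",
                  "attribute: ", paste(bad, collapse = ", ")))
  TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @describeIn EventKindTemplate-class constructor.
#' @param kind,extras,linkage,version see the slot descriptions.  Each entry
#'   of `extras` may omit `allowed` (`NULL`) and `required` (`FALSE`).
#' @export
EventKindTemplate <- function(kind, extras = list(), linkage = "either",
                              version = "1") {
  extras <- lapply(extras, function(x)
    list(name = x$name, type = x$type %||% "text",
         allowed = x$allowed %||% NULL,
         required = isTRUE(x$required)))
  new("EventKindTemplate", kind = kind, extras = extras, linkage = linkage,
      version = as.character(version))
}

.eventRegistry <- new.env(parent = emptyenv())

#' The three built-in event-kind templates
#'
#' @return named list of [EventKindTemplate-class] objects for `sampling`,
#'   `disease_diagnosis` and `death`.
#' @export
builtinEventKinds <- function() {
  list(
    sampling = EventKindTemplate(
      "sampling", linkage = "sample_required", version = "1",
      extras = list()),
    disease_diagnosis = EventKindTemplate(
      "disease_diagnosis", linkage = "donor_required", version = "1",
      extras = list(list(name = "diagnosis_code", type = "diagnosis_code",
                         required = TRUE))),
    death = EventKindTemplate(
      "death", linkage = "donor_required", version = "1",
      extras = list(list(name = "cause_of_death_code", type = "icd10",
                         required = FALSE)))
  )
}

#' Register an event-kind template
#'
#' Once registered, [validateRecordSet()] applies the template's required
#' extras, allowed values and linkage rule to every event carrying that
#' kind, in addition to the generic event rules.  Events of an unregistered
#' kind are validated against the generic rules only and raise a warning
#' finding.
#'
#' @param template an [EventKindTemplate-class].
#' @param replace logical; replacing an existing kind must be explicit.
#' @return the template, invisibly.
#' @export
registerEventKind <- function(template, replace = FALSE) {
  stopifnot(is(template, "EventKindTemplate"))
  validObject(template)
  if (!replace && !is.null(.eventRegistry[[template@kind]]))
    stop("event kind '", template@kind,
         "' is already registered (use replace = TRUE)")
  assign(template@kind, template, envir = .eventRegistry)
  invisible(template)
}

#' @describeIn registerEventKind list all registered templates, keyed by kind.
#' @export
eventKindRegistry <- function() {
  as.list(.eventRegistry)[sort(ls(.eventRegistry))]
}

#' @describeIn registerEventKind restore the registry to the built-ins only.
#' @export
resetEventKinds <- function() {
  rm(list = ls(.eventRegistry), envir = .eventRegistry)
  for (t in builtinEventKinds()) assign(t@kind, t, envir = .eventRegistry)
  invisible(NULL)
}

# one extra-attribute value against its spec; returns NULL or a message
.checkExtraValue <- function(spec, value) {
  v <- as.character(value)
  if (length(v) != 1L || is.na(v))
    return(sprintf("extra attribute '%s' must be a single value", spec$name))
  ok <- switch(spec$type,
    text = TRUE,
    icd10 = isIcd10Code(v),
    diagnosis_code = v %in% .VOCAB$content_diagnosis_keywords || isIcd10Code(v),
    enum = v %in% (spec$allowed %||% character()),
    TRUE)
  if (!is.null(spec$allowed) && spec$type != "enum")
    ok <- ok && v %in% spec$allowed
  if (!ok)
    return(sprintf("extra attribute '%s' has disallowed value '%s'",
                   spec$name, v))
  NULL
}
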