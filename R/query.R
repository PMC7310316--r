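# Availability queries over a RecordSet: the single-store core of a
# sample-locator workflow.  Predicates are structured objects (no query
# language); a query is the conjunction of its predicates, and a sample
# matches when each predicate holds for the sample itself, its linked
# donor, or a linked event, depending on the predicate's target.
#
# The standard references the locator use-case without specifying query
# semantics; everything here (conjunction, missing-value policy, unit
# conversion) is this package's design, documented in the vignette.

.DERIVED_TARGETS <- c("age_at_event", "donor_age_at_sampling")

# age-unit conversion to years for query-side ranges; gestational weeks are
# deliberately absent — a predicate in years never matches a
# gestational-week age
.YEARS_PER_UNIT <- c(years = 1, months = 1 / 12, weeks = 1 / 52.1775,
                     days = 1 / 365.25)

#' Construct a query predicate
#'
#' @param target a MIABIS attribute code, or a derived field:
#'   `"age_at_event"` (age in years derived from any linked event via
#'   [deriveAge()]) or `"donor_age_at_sampling"` (same, restricted to
#'   sampling events).
#' @param op one of `"eq"`, `"in"`, `"range"`, `"exists"`, `"missing"`.
#'   `range` is only valid on dates, decimals and derived ages; its operand
#'   is `c(lo, hi)` (ISO 8601 strings for date targets, years for age
#'   targets).
#' @param operand value, value list, or interval, per `op`.
#' @param missingPolicy `"fail"` (default) or `"pass"`: whether a sample
#'   whose relevant attribute is unrecorded satisfies a positive predicate.
#'   The conservative default suits availability counts.
#' @return a `miabisPredicate` object (a validated list).
#' @examples
#' miabisPredicate("MIABIS-SAMPLE-02", "eq", "Serum")
#' miabisPredicate("age_at_event", "range", c(18, 65))
#' @export
miabisPredicate <- function(target, op, operand = NULL,
                            missingPolicy = c("fail", "pass")) {
  missingPolicy <- match.arg(missingPolicy)
  op <- match.arg(op, c("eq", "in", "range", "exists", "missing"))
  derived <- target %in% .DERIVED_TARGETS
  if (!derived && !target %in% .ATTRIBUTES$code)
    stop("unknown predicate target '", target, "'")
  type <- if (derived) "decimal"
          else .ATTRIBUTES$type[match(target, .ATTRIBUTES$code)]
  if (op == "range") {
    if (!type %in% c("timestamp", "decimal"))
      stop("range predicates are only valid on dates and decimals, not on '",
           target, "'")
    if (length(operand) != 2L) stop("range operand must be c(lo, hi)")
    if (type == "decimal" && operand[1] > operand[2])
      stop("inverted range bounds")
    if (type == "timestamp") {
      lo <- parsePartialTimestamp(operand[1])
      hi <- parsePartialTimestamp(operand[2])
      if (ptCompare(lo, hi) > 0L) stop("inverted range bounds")
    }
  }
  if (op %in% c("eq", "in") && !length(operand))
    stop("'", op, "' predicate needs an operand")
  structure(list(target = target, op = op, operand = operand,
                 missingPolicy = missingPolicy, type = type),
            class = "miabisPredicate")
}

#' Derive a donor's age at an event
#'
#' Returns the recorded age verbatim when the event carries the age
#' encoding; otherwise computes the age from the event date and the donor's
#' birth date at the coarser of the two precisions (so year-precision
#' inputs yield a whole-year difference), in years.  Derived precision
#' never exceeds the coarser input precision.
#'
#' @param event an [Event-class].
#' @param donor the linked [SampleDonor-class] (used for the date encoding).
#' @return a list with `age` (decimal), `unit`, and `source`
#'   (`"recorded"` or the precision the difference was computed at).
#' @examples
#' d <- SampleDonor("D1", "female", birthDate = "1980-05-10")
#' e <- Event("E1", eventDatetime = "2010-05-10T00:00:00", donorRef = "D1")
#' deriveAge(e, d)
#' @export
deriveAge <- function(event, donor = NULL) {
  stopifnot(is(event, "Event"))
  if (!is.na(event@ageAtEvent))
    return(list(age = event@ageAtEvent, unit = event@ageUnit,
                source = "recorded"))
  if (is.null(event@eventDatetime))
    stop("event carries neither an age nor an event date")
  if (is.null(donor) || is.null(donor@birthDate))
    stop("date-encoded event needs the linked donor's birth date")
  b <- donor@birthDate
  e <- event@eventDatetime
  if (ptCompare(e, b) < 0L)
    stop("event date precedes the donor's birth date")
  level <- min(.PRECISION_LEVELS[[ptPrecision(b)]],
               .PRECISION_LEVELS[[ptPrecision(e)]])
  years <- e@year - b@year
  if (level >= 2L && (e@month < b@month ||
      (level >= 3L && e@month == b@month && e@day < b@day)))
    years <- years - 1L
  list(age = as.numeric(years), unit = "years",
       source = names(.PRECISION_LEVELS)[min(level, 3L)])
}

# derived age in years, or numeric(0); conversion constants in
# .YEARS_PER_UNIT
.ageInYears <- function(event, donor) {
  a <- tryCatch(deriveAge(event, donor), error = function(e) NULL)
  if (is.null(a) || is.na(a$age)) return(numeric())
  if (identical(a$source, "recorded")) {
    k <- .YEARS_PER_UNIT[a$unit]
    if (is.na(k)) return(numeric())
    return(a$age * unname(k))
  }
  a$age
}

# recorded values of `pred$target` visible from sample `s`; a list of
# character values, numbers, or PartialTimestamps
.targetValues <- function(pred, s, rs) {
  target <- pred$target
  donor <- if (!is.na(s@donorRef)) rs@donors[[s@donorRef]]
  linkedEvents <- Filter(function(e) {
    (!is.na(e@sampleRef) && e@sampleRef == s@sampleId) ||
      (!is.null(donor) && !is.na(e@donorRef) && e@donorRef == donor@donorId)
  }, rs@events)

  if (target %in% .DERIVED_TARGETS) {
    # donor_age_at_sampling means the age at THIS sample's sampling event,
    # so only events directly referencing the sample qualify
    evs <- if (target == "donor_age_at_sampling")
      Filter(function(e) identical(e@eventKind, "sampling") &&
               !is.na(e@sampleRef) && e@sampleRef == s@sampleId,
             linkedEvents)
    else linkedEvents
    vals <- as.list(unlist(lapply(evs, .ageInYears, donor = donor)))
    return(list(values = vals, recorded = length(vals) > 0L))
  }

  component <- .ATTRIBUTES$component[match(target, .ATTRIBUTES$code)]
  recs <- switch(component,
    sample = list(s),
    donor = if (is.null(donor)) list() else list(donor),
    event = linkedEvents)
  recorded <- any(vapply(recs, function(r) .attrRecorded(target, r),
                         logical(1)))
  out <- list()
  for (r in recs) {
    v <- switch(target,
      "MIABIS-SAMPLEDONOR-01" = r@donorId,
      "MIABIS-SAMPLEDONOR-02" = r@sex,
      "MIABIS-SAMPLEDONOR-03" = r@dataCategories,
      "MIABIS-SAMPLEDONOR-04" = r@birthDate,
      "MIABIS-SAMPLE-01" = r@sampleId,
      "MIABIS-SAMPLE-02" = r@detailedSampleType,
      "MIABIS-SAMPLE-03" = r@storageTemperature,
      "MIABIS-SAMPLE-04" = r@creationDatetime,
      "MIABIS-SAMPLE-05" = if (!is.null(r@anatomicalSite)) r@anatomicalSite@ontology,
      "MIABIS-SAMPLE-06" = if (!is.null(r@anatomicalSite)) r@anatomicalSite@ontologyVersion,
      "MIABIS-SAMPLE-07" = if (!is.null(r@anatomicalSite)) r@anatomicalSite@code,
      "MIABIS-SAMPLE-08" = if (!is.null(r@anatomicalSite)) r@anatomicalSite@description,
      "MIABIS-SAMPLE-09" = if (!is.null(r@anatomicalSite)) r@anatomicalSite@freeText,
      "MIABIS-SAMPLE-10" = r@contentDiagnosis,
      "MIABIS-SAMPLE-11" = r@useRestrictions,
      "MIABIS-EVENT-01" = r@eventId,
      "MIABIS-EVENT-02" = r@eventDatetime,
      "MIABIS-EVENT-03" = r@ageAtEvent,
      "MIABIS-EVENT-04" = r@ageUnit,
      NULL)
    if (is(v, "PartialTimestamp")) out[[length(out) + 1L]] <- v
    else for (vv in v) if (!is.na(vv)) out[[length(out) + 1L]] <- vv
  }
  list(values = out, recorded = recorded)
}

.predicateHolds <- function(pred, s, rs) {
  tv <- .targetValues(pred, s, rs)
  vals <- tv$values
  # "recorded" distinguishes an attribute recorded with no values (an empty
  # list) from one never recorded: only the latter is "missing", and only
  # the latter is forgiven by missingPolicy = "pass"
  if (pred$op == "exists") return(tv$recorded)
  if (pred$op == "missing") return(!tv$recorded)
  if (!tv$recorded)
    return(pred$missingPolicy == "pass")
  if (!length(vals)) return(FALSE)
  hit <- switch(pred$op,
    eq = any(vapply(vals, function(v) {
      if (is(v, "PartialTimestamp"))
        ptCompare(v, parsePartialTimestamp(pred$operand)) == 0L
      else v == pred$operand
    }, logical(1))),
    "in" = any(vapply(vals, function(v)
      as.character(v) %in% as.character(pred$operand), logical(1))),
    range = any(vapply(vals, function(v) {
      if (is(v, "PartialTimestamp")) {
        lo <- parsePartialTimestamp(pred$operand[1])
        hi <- parsePartialTimestamp(pred$operand[2])
        ptCompare(v, lo) >= 0L && ptCompare(v, hi) <= 0L
      } else {
        vn <- as.numeric(v)
        vn >= pred$operand[1] && vn <= pred$operand[2]
      }
    }, logical(1))))
  isTRUE(hit)
}

#' Evaluate an availability query
#'
#' Applies the conjunction (logical AND) of the predicates to every sample
#' in the set.  Adding a predicate can never enlarge the result.  The empty
#' predicate list matches all samples.
#'
#' @param rs a [RecordSet-class].
#' @param predicates a list of [miabisPredicate()] objects.
#' @return a list with `sampleIds` (sorted, deterministic), `nSamples`, and
#'   `nDonors` (distinct donors linked to the matching samples).
#' @examples
#' rs <- generateRecordSet(5, seed = 1)
#' evaluateQuery(rs, list(miabisPredicate("MIABIS-SAMPLEDONOR-02", "eq",
#'                                        "female")))$nSamples
#' @export
evaluateQuery <- function(rs, predicates = list()) {
  stopifnot(is(rs, "RecordSet"))
  if (is(predicates, "miabisPredicate")) predicates <- list(predicates)
  for (p in predicates)
    if (!is(p, "miabisPredicate"))
      stop("predicates must be built with miabisPredicate()")
  hits <- vapply(rs@samples, function(s)
    all(vapply(predicates, .predicateHolds, logical(1), s = s, rs = rs)),
    logical(1))
  matched <- rs@samples[hits]
  ids <- sort(vapply(matched, function(s) s@sampleId, character(1)),
              method = "radix")
  dids <- unique(stats::na.omit(vapply(matched, function(s) s@donorRef,
                                       character(1))))
  dids <- dids[dids %in% names(rs@donors)]
  list(sampleIds = unname(ids), nSamples = length(ids),
       nDonors = length(dids))
}
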