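# Reduced-precision ISO 8601 parsing, rendering and comparison.

#' Construct a PartialTimestamp
#'
#' @param year CE year (required).
#' @param month,day optional calendar components.
#' @param hour,minute,second optional time of day; all three must be given
#'   together (a time of day is complete to seconds).
#' @return a [PartialTimestamp-class] object.
#' @examples
#' PartialTimestamp(1975)
#' PartialTimestamp(2010, 5, 10, 0, 0, 0)
#' @export
PartialTimestamp <- function(year, month = NA, day = NA,
                             hour = NA, minute = NA, second = NA) {
  new("PartialTimestamp",
      year = as.integer(year), month = as.integer(month),
      day = as.integer(day), hour = as.integer(hour),
      minute = as.integer(minute), second = as.integer(second))
}

#' Precision of a partial timestamp
#'
#' @param x a [PartialTimestamp-class].
#' @return one of `"year"`, `"month"`, `"day"`, `"second"` — the finest
#'   component present.
#' @examples
#' ptPrecision(parsePartialTimestamp("2010-05"))
#' @export
ptPrecision <- function(x) {
  stopifnot(is(x, "PartialTimestamp"))
  if (!is.na(x@second)) "second"
  else if (!is.na(x@day)) "day"
  else if (!is.na(x@month)) "month"
  else "year"
}

.PRECISION_LEVELS <- c(year = 1L, month = 2L, day = 3L, second = 4L)

#' Parse a reduced-precision ISO 8601 string
#'
#' Accepts the canonical reduced-precision forms `"YYYY"`, `"YYYY-MM"`,
#' `"YYYY-MM-DD"` and `"YYYY-MM-DDThh:mm:ss"`.  Parsing is strict: malformed
#' strings, impossible calendar dates and gapped precision raise an error
#' naming the offending component.
#'
#' @param text a single non-empty string.
#' @return a [PartialTimestamp-class] whose precision equals the finest
#'   component present; `formatPartialTimestamp()` inverts the parse for
#'   canonical strings.
#' @examples
#' parsePartialTimestamp("1975")
#' parsePartialTimestamp("2010-05-10T00:00:00")
#' @export
parsePartialTimestamp <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(text))
    stop("expected a single non-empty ISO 8601 string")
  pats <- c(
    second = "^([0-9]{4})-([0-9]{2})-([0-9]{2})T([0-9]{2}):([0-9]{2}):([0-9]{2})$",
    day    = "^([0-9]{4})-([0-9]{2})-([0-9]{2})$",
    month  = "^([0-9]{4})-([0-9]{2})$",
    year   = "^([0-9]{4})$"
  )
  for (prec in names(pats)) {
    m <- regmatches(text, regexec(pats[[prec]], text))[[1]]
    if (length(m)) {
      parts <- as.integer(m[-1])
      parts <- c(parts, rep(NA_integer_, 6L - length(parts)))
      out <- tryCatch(
        PartialTimestamp(parts[1], parts[2], parts[3],
                         parts[4], parts[5], parts[6]),
        error = function(e) stop("invalid timestamp '", text, "': ",
                                 conditionMessage(e), call. = FALSE))
      return(out)
    }
  }
  stop("malformed partial timestamp '", text,
       "': expected YYYY[-MM[-DD[Thh:mm:ss]]]")
}

#' Render a partial timestamp as its canonical ISO 8601 string
#'
#' @param x a [PartialTimestamp-class].
#' @return the canonical reduced-precision string; round trips with
#'   [parsePartialTimestamp()].
#' @examples
#' formatPartialTimestamp(PartialTimestamp(2010, 5))
#' @export
formatPartialTimestamp <- function(x) {
  stopifnot(is(x, "PartialTimestamp"))
  switch(ptPrecision(x),
    year   = sprintf("%04d", x@year),
    month  = sprintf("%04d-%02d", x@year, x@month),
    day    = sprintf("%04d-%02d-%02d", x@year, x@month, x@day),
    second = sprintf("%04d-%02d-%02dT%02d:%02d:%02d",
                     x@year, x@month, x@day, x@hour, x@minute, x@second))
}

# numeric components at a given precision level (1..4)
.ptParts <- function(x, level) {
  p <- c(x@year, x@month, x@day, x@hour, x@minute, x@second)
  switch(level, p[1], p[1:2], p[1:3], p)
}

#' Compare two partial timestamps at their coarser precision
#'
#' Comparisons between partial timestamps are made at the coarser of the two
#' precisions (so `"1980"` and `"1980-07-01"` compare equal).  This is the
#' comparison underlying the chronology checks and date-range queries.
#'
#' @param a,b [PartialTimestamp-class] objects.
#' @return `-1L`, `0L` or `1L` as `a` is before, indistinguishable from, or
#'   after `b` at the shared precision.
#' @examples
#' ptCompare(parsePartialTimestamp("1980"), parsePartialTimestamp("1980-07"))
#' @export
ptCompare <- function(a, b) {
  level <- min(.PRECISION_LEVELS[[ptPrecision(a)]],
               .PRECISION_LEVELS[[ptPrecision(b)]])
  pa <- .ptParts(a, level)
  pb <- .ptParts(b, level)
  for (i in seq_along(pa)) {
    if (pa[i] < pb[i]) return(-1L)
    if (pa[i] > pb[i]) return(1L)
  }
  0L
}

setMethod("show", "PartialTimestamp", function(object) {
  cat("PartialTimestamp ", formatPartialTimestamp(object),
      " (", ptPrecision(object), " precision)\n", sep = "")
})
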