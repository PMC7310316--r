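# Per-component CSV tables and the Yes/No/Not-applicable tabulation of
# multi-valued attributes.
#
# Dialect: UTF-8, comma delimiter, quoted fields, mandatory header row;
# headers are the MIABIS attribute codes (plus CODE.slug tabulation columns
# and the linkage fields), making the files self-describing.  Degree signs
# and Unicode minuses in enum values are preserved verbatim.
#
# Multi-valued cells (non-tabulated mode) hold a compact JSON array so that
# "recorded with no values" (`[]`) stays distinct from "not recorded"
# (empty cell).  Tabulated mode expands each closed-vocabulary list
# attribute into one column per printed value with the three-valued
# semantics: Yes = value present, No = value absent on a record that
# carries the attribute, Not applicable = attribute not recorded at all.

.slug <- function(x) {
  s <- tolower(x)
  s <- gsub("[^a-z0-9]+", "_", s)
  gsub("^_+|_+$", "", s)
}

# list attributes that tabulate fully (closed vocabularies)
.TABULATED_CODES <- c("MIABIS-SAMPLEDONOR-03", "MIABIS-SAMPLE-11")

#' Tabulation column specification for a multi-valued attribute
#'
#' For database use, each allowed value of a closed multi-valued attribute
#' is tabulated as an independent column taking Yes/No/Not applicable.
#' Columns are named `CODE.slug` and follow the printed value order.  The
#' content-diagnosis attribute (`MIABIS-SAMPLE-10`) has an open ICD-10
#' value space, so only its three closed keywords tabulate; ICD-10 codes go
#' to the residual column `MIABIS-SAMPLE-10.icd10_codes`.
#'
#' @param code one of `"MIABIS-SAMPLEDONOR-03"`, `"MIABIS-SAMPLE-10"`,
#'   `"MIABIS-SAMPLE-11"`.
#' @return a data.frame with columns `column` (CSV header) and `value` (the
#'   canonical attribute value; `NA` for the residual ICD-10 column).
#' @examples
#' tabulatedColumnSpec("MIABIS-SAMPLE-11")
#' @export
tabulatedColumnSpec <- function(code) {
  vals <- switch(code,
    "MIABIS-SAMPLEDONOR-03" = .VOCAB$data_categories,
    "MIABIS-SAMPLE-11" = .VOCAB$use_restrictions,
    "MIABIS-SAMPLE-10" = .VOCAB$content_diagnosis_keywords,
    stop("attribute '", code, "' is not a tabulatable list attribute"))
  out <- data.frame(column = paste0(code, ".", .slug(vals)), value = vals,
                    stringsAsFactors = FALSE)
  if (code == "MIABIS-SAMPLE-10")
    out <- rbind(out, data.frame(column = "MIABIS-SAMPLE-10.icd10_codes",
                                 value = NA_character_))
  if (anyDuplicated(out$column)) stop("tabulation column slug collision")
  out
}

.listCell <- function(x) {
  if (is.null(x)) "" else as.character(jsonlite::toJSON(as.character(x)))
}

.unlistCell <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NULL)
  as.character(jsonlite::fromJSON(x, simplifyVector = TRUE) %||% character())
}

.cell <- function(x) if (is.null(x) || is.na(x)) "" else as.character(x)
.uncell <- function(x) if (is.na(x) || !nzchar(x)) NA_character_ else x

# expand one list value into the Yes/No/Not applicable columns
.tabulateValue <- function(code, vals) {
  spec <- tabulatedColumnSpec(code)
  keyed <- spec[!is.na(spec$value), ]
  if (is.null(vals)) {
    out <- setNames(rep("Not applicable", nrow(keyed)), keyed$column)
    if (code == "MIABIS-SAMPLE-10") out["MIABIS-SAMPLE-10.icd10_codes"] <- ""
    return(out)
  }
  out <- setNames(ifelse(keyed$value %in% vals, "Yes", "No"), keyed$column)
  if (code == "MIABIS-SAMPLE-10") {
    icd <- vals[!vals %in% keyed$value]
    out["MIABIS-SAMPLE-10.icd10_codes"] <-
      as.character(jsonlite::toJSON(as.character(icd)))
  }
  out
}

# invert .tabulateValue given a named character row
.detabulateValue <- function(code, row) {
  spec <- tabulatedColumnSpec(code)
  keyed <- spec[!is.na(spec$value), ]
  cells <- row[keyed$column]
  bad <- setdiff(unique(cells), c("Yes", "No", "Not applicable"))
  if (length(bad))
    stop("tabulated cell value(s) outside Yes/No/Not applicable for ",
         code, ": ", paste(bad, collapse = ", "))
  if (all(cells == "Not applicable")) {
    if (code == "MIABIS-SAMPLE-10" &&
        nzchar(row[["MIABIS-SAMPLE-10.icd10_codes"]]))
      stop("ICD-10 codes recorded on a Not-applicable content diagnosis")
    return(NULL)
  }
  if (any(cells == "Not applicable"))
    stop("mixed Not applicable and Yes/No cells for ", code)
  vals <- keyed$value[cells == "Yes"]
  if (code == "MIABIS-SAMPLE-10")
    vals <- c(vals, .unlistCell(row[["MIABIS-SAMPLE-10.icd10_codes"]]) %||%
                character())
  as.character(vals)
}

.writeTable <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.csv(df, con, row.names = FALSE, quote = TRUE)
}

.readTable <- function(path) {
  read.csv(path, colClasses = "character", check.names = FALSE,
           fileEncoding = "UTF-8")
}

.ptCell <- function(x) if (is.null(x)) "" else formatPartialTimestamp(x)
.unptCell <- function(x)
  if (is.na(x) || !nzchar(x)) NULL else parsePartialTimestamp(x)

#' Write a RecordSet as per-component CSV tables
#'
#' Writes `donor.csv`, `sample.csv`, `event.csv`, `collection.csv` and
#' `biobank.csv` into `dir`.  With `tabulate = TRUE` the multi-valued
#' attributes (data categories, content diagnosis, use restrictions) expand
#' into Yes/No/Not-applicable indicator columns per
#' [tabulatedColumnSpec()]; otherwise they serialize as JSON-array cells.
#'
#' @param rs a [RecordSet-class].
#' @param dir output directory (created if needed).
#' @param tabulate logical.
#' @return `dir`, invisibly.
#' @seealso [readRecordSetCsv()]
#' @export
writeRecordSetCsv <- function(rs, dir, tabulate = FALSE) {
  stopifnot(is(rs, "RecordSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  donorRow <- function(d) {
    base <- c("MIABIS-SAMPLEDONOR-01" = .cell(d@donorId),
              "MIABIS-SAMPLEDONOR-02" = .cell(d@sex))
    dc <- if (tabulate) .tabulateValue("MIABIS-SAMPLEDONOR-03",
                                       d@dataCategories)
          else c("MIABIS-SAMPLEDONOR-03" = .listCell(d@dataCategories))
    c(base, dc, "MIABIS-SAMPLEDONOR-04" = .ptCell(d@birthDate))
  }
  sampleRow <- function(s) {
    a <- s@anatomicalSite
    av <- function(f) if (is.null(a)) "" else .cell(slot(a, f))
    base <- c("MIABIS-SAMPLE-01" = .cell(s@sampleId),
              "MIABIS-SAMPLE-02" = .cell(s@detailedSampleType),
              "MIABIS-SAMPLE-03" = .cell(s@storageTemperature),
              "MIABIS-SAMPLE-04" = .ptCell(s@creationDatetime),
              "MIABIS-SAMPLE-05" = av("ontology"),
              "MIABIS-SAMPLE-06" = av("ontologyVersion"),
              "MIABIS-SAMPLE-07" = av("code"),
              "MIABIS-SAMPLE-08" = av("description"),
              "MIABIS-SAMPLE-09" = av("freeText"))
    cd <- if (tabulate) .tabulateValue("MIABIS-SAMPLE-10", s@contentDiagnosis)
          else c("MIABIS-SAMPLE-10" = .listCell(s@contentDiagnosis))
    ur <- if (tabulate) .tabulateValue("MIABIS-SAMPLE-11", s@useRestrictions)
          else c("MIABIS-SAMPLE-11" = .listCell(s@useRestrictions))
    c(base, cd, ur, donorRef = .cell(s@donorRef),
      collectionRef = .cell(s@collectionRef))
  }
  eventRow <- function(e) {
    c("MIABIS-EVENT-01" = .cell(e@eventId),
      "MIABIS-EVENT-02" = .ptCell(e@eventDatetime),
      "MIABIS-EVENT-03" = if (is.na(e@ageAtEvent)) "" else
        as.character(e@ageAtEvent),
      "MIABIS-EVENT-04" = .cell(e@ageUnit),
      eventKind = .cell(e@eventKind),
      extraAttributes = if (length(e@extraAttributes))
        as.character(jsonlite::toJSON(e@extraAttributes,
                                      auto_unbox = TRUE, digits = NA))
      else "",
      donorRef = .cell(e@donorRef), sampleRef = .cell(e@sampleRef))
  }
  collectionRow <- function(cl)
    c(id = .cell(cl@id), name = .cell(cl@name),
      biobankRef = .cell(cl@biobankRef))
  biobankRow <- function(b) c(id = .cell(b@id), name = .cell(b@name))

  asTable <- function(records, rowFun, emptyCols) {
    if (!length(records)) {
      df <- as.data.frame(setNames(rep(list(character()), length(emptyCols)),
                                   emptyCols), check.names = FALSE)
      return(df)
    }
    rows <- lapply(records, rowFun)
    as.data.frame(do.call(rbind, rows), check.names = FALSE,
                  stringsAsFactors = FALSE)
  }

  donorCols <- c("MIABIS-SAMPLEDONOR-01", "MIABIS-SAMPLEDONOR-02",
                 if (tabulate) tabulatedColumnSpec("MIABIS-SAMPLEDONOR-03")$column
                 else "MIABIS-SAMPLEDONOR-03",
                 "MIABIS-SAMPLEDONOR-04")
  sampleCols <- c(sprintf("MIABIS-SAMPLE-%02d", 1:9),
                  if (tabulate) c(tabulatedColumnSpec("MIABIS-SAMPLE-10")$column,
                                  tabulatedColumnSpec("MIABIS-SAMPLE-11")$column)
                  else c("MIABIS-SAMPLE-10", "MIABIS-SAMPLE-11"),
                  "donorRef", "collectionRef")
  eventCols <- c(sprintf("MIABIS-EVENT-%02d", 1:4), "eventKind",
                 "extraAttributes", "donorRef", "sampleRef")

  .writeTable(asTable(rs@donors, donorRow, donorCols),
              file.path(dir, "donor.csv"))
  .writeTable(asTable(rs@samples, sampleRow, sampleCols),
              file.path(dir, "sample.csv"))
  .writeTable(asTable(rs@events, eventRow, eventCols),
              file.path(dir, "event.csv"))
  .writeTable(asTable(rs@collections, collectionRow,
                      c("id", "name", "biobankRef")),
              file.path(dir, "collection.csv"))
  .writeTable(asTable(rs@biobanks, biobankRow, c("id", "name")),
              file.path(dir, "biobank.csv"))
  invisible(dir)
}

#' Read a RecordSet from per-component CSV tables
#'
#' Inverts [writeRecordSetCsv()]; tabulated indicator columns are detected
#' from the headers, so both dialects read back without a flag.  A
#' tabulated cell outside Yes/No/Not applicable is an error.
#'
#' @param dir directory containing the component tables.
#' @return a [RecordSet-class].
#' @export
readRecordSetCsv <- function(dir) {
  dt <- .readTable(file.path(dir, "donor.csv"))
  st <- .readTable(file.path(dir, "sample.csv"))
  et <- .readTable(file.path(dir, "event.csv"))
  ct <- .readTable(file.path(dir, "collection.csv"))
  bt <- .readTable(file.path(dir, "biobank.csv"))

  tabulated <- "MIABIS-SAMPLE-11.commercial_use_restriction" %in% names(st)

  donors <- lapply(seq_len(nrow(dt)), function(i) {
    row <- setNames(as.character(dt[i, ]), names(dt))
    dc <- if (tabulated || !"MIABIS-SAMPLEDONOR-03" %in% names(dt))
      .detabulateValue("MIABIS-SAMPLEDONOR-03", row)
    else .unlistCell(row[["MIABIS-SAMPLEDONOR-03"]])
    SampleDonor(donorId = .uncell(row[["MIABIS-SAMPLEDONOR-01"]]),
                sex = .uncell(row[["MIABIS-SAMPLEDONOR-02"]]),
                dataCategories = dc,
                birthDate = .unptCell(row[["MIABIS-SAMPLEDONOR-04"]]))
  })

  samples <- lapply(seq_len(nrow(st)), function(i) {
    row <- setNames(as.character(st[i, ]), names(st))
    av <- vapply(sprintf("MIABIS-SAMPLE-%02d", 5:9),
                 function(k) .uncell(row[[k]]), character(1))
    anat <- if (any(!is.na(av)))
      AnatomicalSite(av[1], av[2], av[3], av[4], av[5]) else NULL
    cd <- if (tabulated) .detabulateValue("MIABIS-SAMPLE-10", row)
          else .unlistCell(row[["MIABIS-SAMPLE-10"]])
    ur <- if (tabulated) .detabulateValue("MIABIS-SAMPLE-11", row)
          else .unlistCell(row[["MIABIS-SAMPLE-11"]])
    Sample(sampleId = .uncell(row[["MIABIS-SAMPLE-01"]]),
           detailedSampleType = .uncell(row[["MIABIS-SAMPLE-02"]]),
           storageTemperature = .uncell(row[["MIABIS-SAMPLE-03"]]),
           creationDatetime = .unptCell(row[["MIABIS-SAMPLE-04"]]),
           anatomicalSite = anat, contentDiagnosis = cd,
           useRestrictions = ur,
           donorRef = .uncell(row[["donorRef"]]),
           collectionRef = .uncell(row[["collectionRef"]]))
  })

  events <- lapply(seq_len(nrow(et)), function(i) {
    row <- setNames(as.character(et[i, ]), names(et))
    extras <- if (nzchar(row[["extraAttributes"]]))
      jsonlite::fromJSON(row[["extraAttributes"]], simplifyVector = FALSE)
    else list()
    age <- row[["MIABIS-EVENT-03"]]
    Event(eventId = .uncell(row[["MIABIS-EVENT-01"]]),
          eventDatetime = .unptCell(row[["MIABIS-EVENT-02"]]),
          ageAtEvent = if (nzchar(age)) as.numeric(age) else NA,
          ageUnit = .uncell(row[["MIABIS-EVENT-04"]]),
          eventKind = .uncell(row[["eventKind"]]),
          extraAttributes = extras,
          donorRef = .uncell(row[["donorRef"]]),
          sampleRef = .uncell(row[["sampleRef"]]))
  })

  collections <- lapply(seq_len(nrow(ct)), function(i)
    SampleCollectionStub(.uncell(ct$id[i]), .uncell(ct$name[i]),
                         .uncell(ct$biobankRef[i])))
  biobanks <- lapply(seq_len(nrow(bt)), function(i)
    BiobankStub(.uncell(bt$id[i]), .uncell(bt$name[i])))

  makeRecordSet(donors = donors, samples = samples, events = events,
                collections = collections, biobanks = biobanks)
}
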