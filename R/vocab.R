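# Printed MIABIS vocabularies and the attribute-code registry.
#
# Enumerated values are stored canonically exactly as printed in the MIABIS
# Sample Donor / Sample / Event attribute tables, including the degree sign
# and the Unicode minus in storage temperatures.  Matching against these
# lists is bit-exact by default; canonicalizeValue() is the opt-in
# normalization helper for common ASCII variants.

#' @import methods
#' @importFrom stats setNames runif na.omit
#' @importFrom utils read.csv write.csv
NULL

.VOCAB <- list(
  sex = c("male", "female", "unknown", "undifferentiated"),

  data_categories = c(
    "biological samples", "survey data", "imaging data",
    "sample donor ethnicity", "medical records", "national registries",
    "genealogical records", "pathology records",
    "physiological/biochemical measurements", "psychological data", "other"
  ),

  # SPREC v3 derived sample-type list (processing-method values merged,
  # processed-sample and digital-sample values added).
  detailed_sample_type = c(
    "Amniotic fluid", "Ascites fluid", "Bile", "Body cavity fluid", "Bone",
    "Bone marrow aspirate", "Bone marrow plasma", "Bone marrow, whole",
    "Breast milk", "Bronchoalveolar lavage", "Buffy coat",
    "Cancer cell lines", "Cerebrospinal fluid", "Cord blood", "Dental pulp",
    "Digital sample", "DNA", "Embryo", "Entire body organ", "Feces",
    "Fetal tissue", "Fibroblasts", "Gas, exhaled ( = breath)",
    "Gastric fluid", "Hair", "Immortalized cell lines", "Isolated microbes",
    "Menstrual blood", "Nail", "Nasal washing", "Pericardial fluid", "PBMC",
    "Placenta", "Plasma", "Pleural fluid", "Primary cells",
    "Postmortem tissue", "Proteins", "Red blood cells", "RNA", "Saliva",
    "Semen", "Serum", "Sputum", "Stem cells and iPS cells", "Swab", "Sweat",
    "Synovial fluid", "Tears", "Teeth", "Tissue (Frozen)", "Tissue (FFPE)",
    "Umbilical cord", "Urine", "Urine sediment", "Vitreous fluid",
    "Whole blood", "Whole blood, dried (e.g., Guthrie cards)"
  ),

  # SPREC v3 derived long-term storage temperatures.
  storage_temperature = c(
    "RT",
    "2°C to 10°C",
    "−18°C to −35°C",
    "−60°C to −85°C",
    "< −135°C",
    "Liquid nitrogen vapor phase",
    "Liquid nitrogen liquid phase",
    "Other"
  ),

  content_diagnosis_keywords = c("Healthy", "Unknown", "Not applicable"),

  use_restrictions = c(
    "Commercial use restriction", "DNA use restriction",
    "Outside EU access restriction", "Xenograft restriction",
    "Other animal work restriction", "Other restriction"
  ),

  age_unit = c("years", "months", "weeks", "days", "gestational weeks")
)

# Pseudonymized, alphanumeric identifier contract (letters, digits and the
# separators dot/dash/underscore found in real barcodes).
.CODED_STRING_PATTERN <- "^[A-Za-z0-9._-]+$"

# Format-level ICD-10 code check (no external catalog consulted; U is not a
# valid chapter letter).
.ICD10_PATTERN <- "^[A-TV-Z][0-9]{2}(\\.[0-9]{1,2})?$"

#' Test the pseudonymized-alphanumeric identifier contract
#'
#' MIABIS donor, sample and event identifiers must be pseudonymized
#' alphanumeric codes.  The syntactic contract enforced here is
#' `[A-Za-z0-9._-]+`; pseudonymization itself is the data producer's duty.
#'
#' @param x character vector.
#' @return logical vector, `TRUE` where `x` satisfies the contract.
#' @examples
#' isCodedString(c("D0001", "S-12_3.4", "bad id!", ""))
#' @export
isCodedString <- function(x) {
  !is.na(x) & nzchar(x) & grepl(.CODED_STRING_PATTERN, x)
}

#' Format-level ICD-10 code check
#'
#' Checks the shape `[A-TV-Z][0-9]{2}(.[0-9]{1,2})?` (e.g. `"C50.9"`).  No
#' external ICD-10 catalog is consulted; catalog validation is a pluggable
#' concern outside this package.
#'
#' @param x character vector of candidate codes.
#' @return logical vector.
#' @examples
#' isIcd10Code(c("C50.9", "A00", "U07.1", "X999"))
#' @export
isIcd10Code <- function(x) {
  !is.na(x) & grepl(.ICD10_PATTERN, x)
}

# ---------------------------------------------------------------------------
# Attribute registry: every attribute carries its MIABIS code.

.ATTRIBUTES <- data.frame(
  code = c(
    sprintf("MIABIS-SAMPLEDONOR-%02d", 1:4),
    sprintf("MIABIS-SAMPLE-%02d", 1:11),
    sprintf("MIABIS-EVENT-%02d", 1:4)
  ),
  component = c(rep("donor", 4), rep("sample", 11), rep("event", 4)),
  name = c(
    "Sample donor ID", "Sex", "Data categories", "Birth date",
    "Sample ID", "Detailed sample type", "Sample storage temperature",
    "Sample creation date and time", "Anatomical site ontology",
    "Anatomical site ontology version", "Anatomical site ontology code",
    "Anatomical site ontology description", "Anatomical site free text",
    "Sample content diagnosis", "Use restrictions",
    "Event ID", "Event date and time", "Age at event", "Age at event unit"
  ),
  type = c(
    "coded", "enum", "list", "timestamp",
    "coded", "enum", "enum", "timestamp", "string", "coded", "coded",
    "string", "string", "list", "list",
    "coded", "timestamp", "decimal", "enum"
  ),
  vocabulary = c(
    NA, "sex", "data_categories", NA,
    NA, "detailed_sample_type", "storage_temperature", NA, NA, NA, NA,
    NA, NA, "content_diagnosis_keywords", "use_restrictions",
    NA, NA, NA, "age_unit"
  ),
  stringsAsFactors = FALSE
)

#' MIABIS attribute registry
#'
#' The model exposes exactly the attribute codes
#' `MIABIS-SAMPLEDONOR-01..04`, `MIABIS-SAMPLE-01..11` and
#' `MIABIS-EVENT-01..04`; each attribute carries a component-specific prefix
#' and a unique identifier, and scalar attributes hold at most one value.
#'
#' @return a data.frame with columns `code`, `component`, `name`, `type` and
#'   `vocabulary` (the name of the closed value list for enumerated
#'   attributes, `NA` otherwise).
#' @examples
#' miabisAttributes()[, c("code", "name")]
#' @export
miabisAttributes <- function() .ATTRIBUTES

#' Allowed values of an enumerated MIABIS attribute
#'
#' @param code a MIABIS attribute code (e.g. `"MIABIS-SAMPLE-03"`) or a
#'   vocabulary name (e.g. `"storage_temperature"`).
#' @return character vector of canonical allowed values, exactly as printed
#'   in the attribute tables.  For the open-valued content-diagnosis
#'   attribute the three closed keywords are returned (ICD-10 codes are
#'   additionally allowed and checked by format).
#' @examples
#' miabisVocabulary("MIABIS-EVENT-04")
#' @export
miabisVocabulary <- function(code) {
  if (code %in% names(.VOCAB)) return(.VOCAB[[code]])
  i <- match(code, .ATTRIBUTES$code)
  if (is.na(i) || is.na(.ATTRIBUTES$vocabulary[i]))
    stop("no closed vocabulary for '", code, "'")
  .VOCAB[[.ATTRIBUTES$vocabulary[i]]]
}

# fold a value for lenient matching: unify dash variants to "-", drop the
# degree sign/"C", squeeze spaces, lowercase
.foldValue <- function(x) {
  x <- gsub("[−–—-]", "-", x)
  x <- gsub("°", "", x)
  x <- gsub("(?i)([0-9])\\s*c\\b", "\\1", x, perl = TRUE)
  x <- gsub("[[:space:]]+", "", x)
  tolower(x)
}

#' Map common ASCII variants of enum values to their canonical form
#'
#' Canonical enum values use the degree sign and the Unicode minus as
#' printed; this opt-in helper maps lenient spellings such as
#' `"-18 to -35C"` or case variants onto the canonical value.  Values with
#' no canonical counterpart are returned unchanged, so validation will still
#' flag them.
#'
#' @param code MIABIS attribute code or vocabulary name.
#' @param x character vector of raw values.
#' @return character vector of the same length with recognized variants
#'   replaced by canonical values.
#' @examples
#' canonicalizeValue("MIABIS-SAMPLE-03", "-18C to -35C")
#' canonicalizeValue("MIABIS-SAMPLEDONOR-02", "Female")
#' @export
canonicalizeValue <- function(code, x) {
  vocab <- miabisVocabulary(code)
  i <- match(.foldValue(x), .foldValue(vocab))
  out <- ifelse(is.na(i), x, vocab[i])
  out
}
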