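Package: miabis
Title: MIABIS Sample, Sample Donor and Event Data Model with Validation,
    Profiles, Serialization and Availability Queries
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reference implementation of the MIABIS (Minimum Information
    About BIobank data Sharing) individual-level terminology extension for
    samples, sample donors and events. Provides S4 record types carrying the
    MIABIS attribute codes, reduced-precision ISO 8601 timestamps, a
    constraint-validation engine for every printed attribute-table rule,
    use-case profiles that tighten the generic model, canonical JSON and
    per-component CSV serialization including the Yes/No/Not-applicable
    tabulation of multi-valued attributes, an availability-query evaluator
    in the style of the BBMRI-ERIC Sample Locator, a synthetic record-set
    generator with rule-targeted mutation, and a minimal attribute-level
    mapping to FHIR-shaped Specimen and Patient documents.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
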