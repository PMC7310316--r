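---
title: "The MIABIS sample/donor/event model: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MIABIS sample/donor/event model: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miabis)
```

## The model and its assumptions

MIABIS Core describes biobanks, sample collections and studies at an
aggregated level. The individual-level extension implemented here adds
three components — **Sample Donor**, **Sample** and **Event** — so that
biobanks can exchange, validate and query per-sample and per-donor
metadata. The model's own guiding assumptions carry through the package:
it covers human samples only, carries no sample-type-specific attributes,
describes the *current* state of a stored sample (no processing history),
and keeps each component independently searchable, with the only mandatory
dependency being sample to donor.

Records are S4 objects (`SampleDonor`, `Sample`, `Event`, plus
`BiobankStub`/`SampleCollectionStub` carrying only linkage identifiers,
since the full Core attribute sets are out of scope). A `RecordSet` holds
the five ID-keyed record lists and is the unit of validation,
serialization and querying. Two layers of checking are deliberately kept
apart:

* **structural validity** (S4 validity methods): slot types, scalar
  lengths, the no-gap rule of partial timestamps — violated structure
  cannot be represented at all;
* **conformance** (`validateRecordSet()`): everything the attribute
  tables require — reported as findings, never thrown, so that
  non-conformant sets can be loaded, diagnosed and repaired.

`makeRecordSet()` therefore only builds ID indexes and enforces ID
uniqueness. The uniqueness scope follows the tables' wording "within a
sample collection": a sample ID must be unique inside its collection when
`collectionRef` is set, and unique across the whole set otherwise; donor,
event, collection and biobank IDs are unique per set. This choice is a
design decision and is stated here rather than buried in code.

## Partial timestamps

Dates in the model are reduced-precision ISO 8601: `"1975"`,
`"2010-05"`, `"2010-05-10"` or `"2010-05-10T13:45:00"`. The
`PartialTimestamp` class stores present components and derives its
precision (`year`, `month`, `day`, `second`); a time of day is always
complete to seconds, matching the printed `yyyy-mm-ddThh:mm:ss` format.
Parsing is strict (no locale heuristics, no partial times), and parsing
inverts rendering on every canonical string.

All comparisons between two partial timestamps happen **at the coarser of
the two precisions**: `"1980"` and `"1980-07-01"` are indistinguishable.
This single convention drives the chronology warnings, date-range queries
and age derivation, and guarantees that no operation fabricates precision
the data does not carry.

## The rule table

Every constraint printed in the attribute tables is one registered rule;
`explainRule()` returns each rule's card, quoting the constraint wording
it enforces (rules the standard does not print are marked
`"design decision"`). The severity model: printed constraints are errors;
anything else is at most a warning.

| Rule | Severity | Enforces |
|------|----------|----------|
| R-DONOR-REQ, R-SAMPLE-REQ, R-EVENT-REQ | error | required attributes (cardinality 1 / asterisk-marked) |
| R-ID-CODED | error | pseudonymized alphanumeric identifiers |
| R-EVENT-XOR | error | event date XOR age at event |
| R-EVENT-AGEUNIT | error | age unit required with age at event |
| R-DONOR-BIRTHDATE | error | birth date required when a date-encoded event is linked |
| R-ANAT-PAIR | error | anatomical-site ontology + version pairing |
| R-EVENT-LINK | error | every event references a sample and/or donor |
| R-ENUM, R-ICD10 | error | vocabulary closure; ICD-10 code format |
| R-REF | error | referential integrity (design decision) |
| R-TMPL-REQ, R-TMPL-LINK | error | event-kind template extras and linkage |
| R-LIST-DUP, R-CHRONO, R-EVENT-KIND, R-DEATH-UNIQUE | warning | list hygiene, chronology, unregistered kinds, one death per donor |

Decisions worth spelling out:

* **Birth-date conditionality.** The donor table gives birth date
  cardinality 0, while the data-model figure marks it conditionally
  required when an exact event date is used. The conditional rule wins:
  `R-DONOR-BIRTHDATE` fires for *any* precision of event date, and the
  required birth date may itself be partial. The stricter reading — a
  day-precision event date demands a day-precision birth date — is
  available behind `strictBirthdate = TRUE` (CLI `--strict-birthdate`),
  default off.
* **Free text and the pairing rule.** The tables attach the 05/06 pairing
  wording to every anatomical-site row including the free-text row, but
  free text exists precisely for unknown or insufficient information, so
  free text alone does **not** trigger the pairing requirement here;
  ontology, version, code or description do.
* **ICD-10 checking is format-level** (`[A-TV-Z][0-9]{2}(\.[0-9]{1,2})?`,
  `U` excluded): no external catalog is consulted, keeping the package
  download-free; catalog validation is a caller concern.
* **Chronology is a warning** (`R-CHRONO`): the standard never states it;
  it exists to catch fixture and data-entry accidents, compared at the
  coarser precision as above.

Findings are plain data.frames with a stable sort (component, record ID,
rule ID), making `validateRecordSet()` a pure, reproducible function of
its input.

## Event-kind templates

The Event component is intentionally minimal — ID, one time encoding,
and links — and is specialized by registered kind templates. Templates
are strictly additive: generic rules always apply. The three built-ins
mirror the standard's use-case examples:

* `sampling` — ties a sample's creation to a time point; a sample
  reference is required;
* `disease_diagnosis` — donor-level; requires a `diagnosis_code` extra in
  the same value space as the content-diagnosis attribute
  (keyword or ICD-10-shaped code);
* `death` — donor-level; optional ICD-10 `cause_of_death_code`; at most
  one per donor, enforced as a warning because it is an inference from
  the semantics of death, not a printed rule.

The built-ins are versioned (`@version`) so a deployment can replace them
with richer attribute lists declaratively — templates load from the same
config dialect as profiles — without any API change. Events of an
unregistered kind validate against the generic rules only and raise a
warning, not an error.

## Profiles

A profile is data, not code: a YAML/JSON document with `cardinality`,
`required`, `values` and `units` keys. The load-time invariant is that a
profile may only *tighten* the generic model — raise a linkage minimum to
1, promote an optional attribute, shrink a value set. Anything else
(a value outside the printed vocabulary, a cardinality of 0) is a load
error naming the offending entry. Consequently the headline monotonicity
property holds by construction and is still tested empirically:
`validateRecordSet(rs)` is always a subset of
`validateAgainstProfile(rs, p)`, whose extra findings carry `P-`-prefixed
rule IDs. Merging profiles unions cardinalities and promotions and
intersects value restrictions; an empty intersection (conflicting fixed
values) fails at merge time, and merging is commutative where
restrictions are disjoint. Conditional restrictions ("if the sample type
is DNA then …") are out of scope for this version, as only unconditional
restrictions are described for the profile mechanism.

## Serialization

**Canonical JSON.** One document per record set; attribute keys are the
MIABIS codes. Keys are sorted, component arrays are sorted bytewise by
record ID, and multi-valued attributes are stored canonically in
printed-value order, so structurally equal sets produce byte-identical
documents. The subtlest dialect choice in the whole package is the
three-state semantics of multi-valued attributes: **not recorded**
(absent key) is different from **recorded with no values** (empty array),
and both round trip.

**CSV.** One UTF-8, comma-delimited, quoted, headered table per component
(`donor.csv`, `sample.csv`, `event.csv`, `collection.csv`,
`biobank.csv`); headers are the attribute codes, so files are
self-describing; degree signs and Unicode minuses in enum values are
preserved verbatim. Without tabulation, list attributes serialize as
compact JSON-array cells (`[]` = recorded empty, empty cell = not
recorded).

**Tabulation.** For flat database use, each closed-list attribute expands
into one indicator column per printed value (`CODE.slug`, lower-snake
slugs, collision-checked at load), taking `Yes` (value present), `No`
(absent on a record that carries the attribute) or `Not applicable`
(attribute not recorded). This reproduces the published tabulation of the
Use-restrictions attribute and extrapolates the identical scheme to Data
categories. Content diagnosis cannot be fully tabulated — its value space
is open (any ICD-10 code) — so its three closed keywords tabulate and
ICD-10 codes go to a residual `MIABIS-SAMPLE-10.icd10_codes` JSON-array
column; the transform stays bijective. Detabulation rejects any cell
outside the three allowed values.

## Availability queries

The locator use-case motivates the query evaluator, but no query
semantics are published; everything here is this package's design,
flagged as such. A query is a conjunction of typed predicates (`eq`,
`in`, `range`, `exists`, `missing`); a sample matches when each predicate
holds for the sample, its donor, or a linked event, per the predicate's
target. Specifics:

* `missingPolicy` defaults to `fail`: an unrecorded attribute does not
  satisfy a positive predicate — conservative for availability counts. A
  recorded-but-empty list is *not* missing: it fails positive predicates
  under either policy and satisfies `exists`.
* Age ranges are expressed in years; recorded ages convert with
  months/12, weeks/52.1775, days/365.25. Gestational-week ages are never
  converted — a predicate in years never matches one.
* `donor_age_at_sampling` uses only sampling events that directly
  reference the sample in question, so a donor's other samples do not
  inherit its age; `age_at_event` considers any linked event.
* `deriveAge()` returns a recorded age verbatim; otherwise it subtracts
  birth date from event date at the coarser precision (whole years:
  anniversary arithmetic at day precision, month difference `%/% 12` at
  month precision, year difference at year precision). Derived precision
  never exceeds the coarser input. An event date before the birth date is
  an error.

Results are deterministic: sorted sample IDs plus `nSamples` and
`nDonors` (distinct donors of the matching samples).

## Synthetic data and the mutation suite

`generateRecordSet()` produces conformant sets by construction: values
drawn uniformly from the printed vocabularies (a `realism` preset skews
sample types toward common biobank holdings — whole blood, serum, plasma,
DNA — with no claim of epidemiological realism), partial-date precisions
mixed deliberately (40/20/30/10% year/month/day/second), both time
encodings for events with birth dates supplied wherever a date-encoded
event demands one, and chronology respected by making event and creation
years strictly exceed the birth year. Donor and sample IDs use the
`D0001`/`S0001` style; event IDs are random hex, following the standard's
note that event IDs are random identifiers minted by the database.
All randomness is seeded and isolated from the caller's RNG; identical
seeds give byte-identical canonical JSON.

What the generator does **not** emulate — longitudinal disease
trajectories, realistic missingness patterns, correlated attributes,
free-text noise — bounds what green tests prove: conformance machinery
and transforms are exercised, not epidemiology.

`mutateRecordSet()` is the one-knockout companion: it breaks exactly one
registered rule (erroring explicitly when the fixture has nothing to
break, never silently no-opping). One violation is declared as an
entailment: unlinking a templated event necessarily breaks both the
generic linkage rule and the template's (`ruleEntailments()`).

Problem sizes used by the test suite — a 10-donor/20-sample/20-event
knockout fixture, 100 generator seeds, 200 record-set/profile pairs, 50
round-trip fixtures, 100 query instances against a full-scan oracle, and
1000 random precision mixes for age derivation — were chosen as the
smallest sizes at which every code path and precision combination is
exercised repeatedly.

## FHIR mapping

`toFhir()` emits one Specimen-shaped document per sample and one
Patient-shaped document per donor from a declarative mapping table. The
only mapping fixed by the standard is the anatomical-site ontology code to
`collection.bodySite.coding.code`; the remaining default entries
(identifiers, sex to `Patient.gender`, birth and collection dates,
sample type) are implementer-chosen and labeled as such. Output is
"FHIR-shaped": structurally valid nested JSON in which `coding` is a
single object rather than an array, so the published dotted path
addresses the code directly; full profile/terminology conformance is
explicitly out of scope. Unmapped attributes are never silently dropped —
the coverage report partitions every attribute code into mapped and
unmapped exactly once.

## Numerical and degenerate-input choices

* Ages are decimals stored to 4 decimal places (gestational weeks imply
  sub-integer ages); unit conversion constants are documented above.
* Empty record sets are valid everywhere: they serialize to empty
  component arrays, query to empty results, and produce zero FHIR
  documents with an empty coverage report.
* Bytewise (`radix`) ordering is used for all ID sorts, making output
  locale-independent.
* Enum matching is bit-exact against the printed values (including `°C`
  and Unicode minuses); `canonicalizeValue()` is the opt-in lenient
  mapper for ASCII variants. Bit-exact interchange beats lenient parsing
  as a default.

## Known limitations

* Ontology codes are checked for shape, not existence (no ICD-10/ICD-O-3
  catalogs); storage-temperature/sample-type plausibility is not checked.
* The query evaluator is a single-store engine: federation, aggregate
  responses and disclosure control (k-anonymity on counts) are outside
  its scope.
* The built-in event templates implement the minimal cores described for
  the three example events, not full supplementary attribute lists; they
  are versioned for replacement.
* FHIR output is structural; OpenEHR/OMOP mappings are not attempted.
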