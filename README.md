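# miabis

An R implementation of the MIABIS (Minimum Information About BIobank data
Sharing) individual-level terminology extension: the **Sample Donor**,
**Sample** and **Event** components, their linked generic data model, and
the machinery biobanks need around them — constraint validation, use-case
profiles, standard serializations, availability queries, and a minimal
FHIR mapping.

## Who this is for

Biobank informaticians and catalog developers who exchange individual-level
sample and donor metadata between biobank information systems, sample
locators and tissue directories. MIABIS Core describes biobanks,
collections and studies in aggregate; this extension describes each sample
and donor individually, so that availability queries ("serum from female
donors aged 29–31 at sampling") can be answered precisely.

## The model in brief

Every attribute carries a stable coded identifier with a component prefix:

| Component    | Codes                   | Required attributes            |
|--------------|-------------------------|--------------------------------|
| Sample Donor | MIABIS-SAMPLEDONOR-01..04 | donor ID, biological sex     |
| Sample       | MIABIS-SAMPLE-01..11    | sample ID, detailed sample type |
| Event        | MIABIS-EVENT-01..04     | event ID                       |

Scalar attributes hold at most one value; multi-valued attributes (data
categories, content diagnosis, use restrictions) have cardinality 0…n.
Samples link to donors and collections; events link to a sample and/or a
donor and carry **either** an event date (reduced-precision ISO 8601, down
to a bare year) **or** an age at event with its unit — never both. A
donor's birth date becomes required as soon as a date-encoded event is
linked to them. Sample types and storage temperatures use SPREC-v3-derived
closed vocabularies. Conditional rules (anatomical-site ontology pairing,
age-unit requirement, …) are enforced by a rule engine whose findings cite
the constraint wording they implement.

**Profiles** tighten the generic model for a use-case — raise a linkage
cardinality from 0…n to 1…n (every sample must have its donor), promote
optional attributes to required, or restrict value sets (age unit fixed to
`years`) — and can never relax it.

## Worked example

```r
library(miabis)

rs <- makeRecordSet(
  donors  = list(SampleDonor("D0001", "female", birthDate = "1980-05-10")),
  samples = list(Sample("S0001", "Serum", donorRef = "D0001",
                        anatomicalSite = AnatomicalSite("ICD-O-3", "3.2",
                                                        "C50.9"))),
  events  = list(Event("a1b2c3d4e5f6", eventDatetime = "2010-05-10T00:00:00",
                       eventKind = "sampling",
                       donorRef = "D0001", sampleRef = "S0001")))
rs
#> MIABIS RecordSet: 1 donor(s), 1 sample(s), 1 event(s), 0 collection(s), 0 biobank(s)

validateRecordSet(rs)          # zero rows: the set is conformant
deriveAge(events(rs)[[1]], donors(rs)[[1]])
#> $age
#> [1] 30
#> $unit
#> [1] "years"
#> $source
#> [1] "day"

evaluateQuery(rs, list(miabisPredicate("MIABIS-SAMPLE-02", "eq", "Serum")))
#> $sampleIds
#> [1] "S0001"
#> $nSamples
#> [1] 1
#> $nDonors
#> [1] 1

toFhir(rs)$specimens[[1]]$collection$bodySite$coding$code
#> [1] "C50.9"
```

Breaking a rule is reported, never thrown:

```r
bad <- mutateRecordSet(generateRecordSet(10, seed = 42), "R-EVENT-XOR",
                       seed = 7)
formatFindings(validateRecordSet(bad))
#> [1] "[error] R-EVENT-XOR event/50ac999ace0e: both event date and age at event are recorded"
explainRule("R-EVENT-XOR")$anchor
#> [1] "\"Use either age at event or event date and time, not both\""
```

A command-line front end wrapping the same functions ships at
`inst/cli/miabis.R` (subcommands `validate`, `profile-check`, `tabulate`,
`detabulate`, `generate`, `mutate`, `query`, `to-fhir`, `explain-rule`).

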