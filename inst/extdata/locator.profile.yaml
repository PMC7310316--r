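# Sample-locator style use-case profile: every sample must carry minimal
# donor information (linkage tightened from 0..n to 1..n) and donor age is
# given in years.
name: locator
description: >-
  Availability-query deployment profile: donor required per sample, age
  unit fixed to years.
cardinality:
  sample.donor: 1
units:
  MIABIS-EVENT-04:
    - years
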