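# Example availability query: serum samples from female donors.
- target: MIABIS-SAMPLE-02
  op: eq
  operand: Serum
- target: MIABIS-SAMPLEDONOR-02
  op: eq
  operand: female
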