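id: EHR-OBSERVATION.ecg_test_result.v0
class: OBSERVATION
provenance: reused
aliases:
  - ecg
items:
  - label: Data
    name: RR Rate
    value_kind: quantity
    units: ms
    range:
      - 400.0
      - 1500.0
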