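id: EHR-OBSERVATION.substance_use-alcohol.v1
class: OBSERVATION
provenance: reused
items:
  - label: Data
    name: Frequency
    value_kind: quantity
    units: per week
    range:
      - 0.0
      - 50.0
  - label: Data
    name: Amount
    value_kind: quantity
    units: units
    range:
      - 0.0
      - 30.0
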