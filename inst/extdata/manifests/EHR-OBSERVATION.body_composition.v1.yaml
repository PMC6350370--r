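id: EHR-OBSERVATION.body_composition.v1
class: OBSERVATION
provenance: reused
items:
  - label: Data
    name: Fat mass
    value_kind: quantity
    units: '%'
    range:
      - 5.0
      - 60.0
  - label: Data
    name: Lean body mass
    value_kind: quantity
    units: kg
    range:
      - 20.0
      - 80.0
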