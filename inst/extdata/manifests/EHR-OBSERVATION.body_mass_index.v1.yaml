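id: EHR-OBSERVATION.body_mass_index.v1
class: OBSERVATION
provenance: reused
items:
  - label: Data
    name: Body mass index
    value_kind: quantity
    units: kg/m2
    range:
      - 12.0
      - 60.0
  - label: Data
    name: Body free mass index
    value_kind: quantity
    units: kg/m2
    range:
      - 5.0
      - 30.0
  - label: Events
    name: Any event
    value_kind: text
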