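id: EHR-OBSERVATION.waist_circumference.v1
class: OBSERVATION
provenance: reused
items:
  - label: Data
    name: Waist circumference
    value_kind: quantity
    units: cm
    range:
      - 50.0
      - 160.0
  - label: Events
    name: Any event
    value_kind: text
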