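id: EHR-OBSERVATION.housing_condition.v0
class: OBSERVATION
provenance: new
aliases:
  - housing condition
items:
  - label: Data
    name: Suitability (participant)
    value_kind: score
    range:
      - 0.0
      - 10.0
  - label: Data
    name: Suitability (investigator)
    value_kind: score
    range:
      - 0.0
      - 10.0
  - label: Data
    name: Number of steps
    value_kind: score
    range:
      - 0.0
      - 50.0
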