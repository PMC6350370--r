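id: EHR-OBSERVATION.gds-15_questionnaire.v0
class: OBSERVATION
provenance: new
aliases:
  - gds-15
  - psychological state
items:
  - label: Data
    name: Total score
    value_kind: score
    range:
      - 0.0
      - 15.0
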