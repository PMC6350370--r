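id: EHR-OBSERVATION.katz_index_questionnaire.v0
class: OBSERVATION
provenance: new
aliases:
  - katz index
  - functional capacity
items:
  - label: Data
    name: Total Score
    value_kind: score
    range:
      - 0.0
      - 6.0
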