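id: EHR-OBSERVATION.lawdon_adl_questionnaire.v0
class: OBSERVATION
provenance: new
aliases:
  - lawton adl
items:
  - label: Data
    name: Total score
    value_kind: score
    range:
      - 0.0
      - 8.0
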