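id: EHR-EVALUATION.recommendation.v1
class: EVALUATION
provenance: reused
aliases:
  - interventions
items:
  - label: Data
    name: Recommendation
    value_kind: text
  - label: Data
    name: Rationale
    value_kind: text
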