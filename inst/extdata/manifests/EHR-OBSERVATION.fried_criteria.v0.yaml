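id: EHR-OBSERVATION.fried_criteria.v0
class: OBSERVATION
provenance: new
aliases:
  - frailty
  - general condition
items:
  - label: Data
    name: Low physical activity
    value_kind: boolean
  - label: Data
    name: Exhaustion
    value_kind: boolean
  - label: Data
    name: Weight loss
    value_kind: boolean
  - label: Data
    name: Index
    value_kind: coded
    codes:
      - non-frail
      - pre-frail
      - frail
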