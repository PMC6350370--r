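id: EHR-EVALUATION.gait_balance_evaluation.v0
class: EVALUATION
provenance: new
aliases:
  - physical condition
items:
  - label: Data
    name: Single foot standing
    value_kind: quantity
    units: s
    range:
      - 0.0
      - 60.0
  - label: Data
    name: Time Get up and go
    value_kind: quantity
    units: s
    range:
      - 0.0
      - 120.0
  - label: Data
    name: Gait speed 4m
    value_kind: quantity
    units: m/s
    range:
      - 0.0
      - 3.0
  - label: Data
    name: Raise from the chair 5 times
    value_kind: quantity
    units: s
    range:
      - 0.0
      - 120.0
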