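id: EHR-OBSERVATION.body_weight.v2
class: OBSERVATION
provenance: reused
aliases:
  - body weight
  - weight
metadata:
  author: community clinical models program
  purpose: Record the body weight of an individual
items:
  - label: Data
    name: Weight
    value_kind: quantity
    units: kg
    range:
      - 30.0
      - 150.0
  - label: Data
    name: Comment
    value_kind: text
  - label: Events
    name: Any event
    value_kind: text
  - label: State
    name: State of dress
    value_kind: coded
    codes:
      - lightly clothed
      - fully clothed
      - naked
  - label: Protocol
    name: Device
    value_kind: coded
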