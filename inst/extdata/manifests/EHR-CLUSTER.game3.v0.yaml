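id: EHR-CLUSTER.game3.v0
class: CLUSTER
provenance: new
aliases:
  - game3
metadata:
  note: 'Synthetic identifier: the archetype''s existence is stated but its name is
    not published'
items:
  - label: Data
    name: Max force
    value_kind: quantity
    units: 'N'
    range:
      - 0.0
      - 500.0
  - label: Data
    name: Average max force
    value_kind: quantity
    units: 'N'
    range:
      - 0.0
      - 500.0
  - label: Data
    name: Average endurance
    value_kind: quantity
    units: s
    range:
      - 0.0
      - 300.0
  - label: Data
    name: Max endurance
    value_kind: quantity
    units: s
    range:
      - 0.0
      - 300.0
  - label: Data
    name: Average score
    value_kind: quantity
    range:
      - 0.0
      - 1000.0
  - label: Data
    name: Max score
    value_kind: quantity
    range:
      - 0.0
      - 1000.0
  - label: Data
    name: Average game duration
    value_kind: quantity
    units: min
    range:
      - 0.0
      - 60.0
  - label: Data
    name: Max game duration
    value_kind: quantity
    units: min
    range:
      - 0.0
      - 60.0
  - label: Data
    name: Height over game duration
    value_kind: quantity
    range:
      - 0.0
      - 100.0
  - label: Data
    name: Distance over game duration
    value_kind: quantity
    range:
      - 0.0
      - 100.0
  - label: Data
    name: Speed over game duration
    value_kind: quantity
    range:
      - 0.0
      - 100.0
  - label: Data
    name: Lives over game duration
    value_kind: quantity
    range:
      - 0.0
      - 10.0
  - label: Data
    name: Force over game duration
    value_kind: quantity
    range:
      - 0.0
      - 500.0
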