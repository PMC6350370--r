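id: EHR-OBSERVATION.blood_pressure.v1
class: OBSERVATION
provenance: reused
aliases:
  - blood pressure
metadata:
  author: community clinical models program
  purpose: Record the systemic arterial blood pressure
items:
  - label: Data
    name: Systolic
    value_kind: quantity
    units: mm[Hg]
    range:
      - 70.0
      - 250.0
  - label: Data
    name: Diastolic
    value_kind: quantity
    units: mm[Hg]
    range:
      - 40.0
      - 150.0
  - label: Data
    name: Pulse Pressure
    value_kind: quantity
    units: mm[Hg]
    range:
      - 10.0
      - 120.0
  - label: Data
    name: Comment
    value_kind: text
  - label: Events
    name: Any event
    value_kind: text
  - label: State
    name: Position
    value_kind: coded
    codes:
      - sitting
      - standing
      - lying
  - label: Protocol
    name: Device
    value_kind: coded
  - label: Protocol
    name: Cuff size
    value_kind: coded
    codes:
      - adult
      - large adult
      - paediatric
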