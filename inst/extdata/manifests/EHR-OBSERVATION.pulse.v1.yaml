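id: EHR-OBSERVATION.pulse.v1
class: OBSERVATION
provenance: modified
aliases:
  - heart rate
  - pulse
metadata:
  note: Extended with a heart-rate variability field for daily device aggregates
items:
  - label: Data
    name: Rate
    value_kind: quantity
    units: /min
    range:
      - 30.0
      - 220.0
  - label: Data
    name: Variability
    value_kind: quantity
    units: ms
    range:
      - 0.0
      - 200.0
  - label: State
    name: Position
    value_kind: coded
    codes:
      - sitting
      - standing
      - lying
      - walking
  - label: Events
    name: Maximum
    value_kind: quantity
    units: /min
    range:
      - 30.0
      - 250.0
  - label: Events
    name: Any event
    value_kind: text
  - label: Protocol
    name: Device
    value_kind: coded
added_items:
  - label: Data
    name: Variability
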