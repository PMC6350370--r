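id: EHR-OBSERVATION.respiration.v1
class: OBSERVATION
provenance: modified
aliases:
  - respiration rate
metadata:
  note: Extended with subject position during acquisition and the measuring device
items:
  - label: Data
    name: Rate
    value_kind: quantity
    units: /min
    range:
      - 5.0
      - 60.0
  - label: Data
    name: Depth
    value_kind: coded
    codes:
      - shallow
      - normal
      - deep
  - label: State
    name: Position
    value_kind: coded
    codes:
      - sitting
      - standing
      - lying
      - walking
  - label: Events
    name: Any event
    value_kind: text
  - label: Protocol
    name: Device
    value_kind: coded
added_items:
  - label: State
    name: Position
  - label: Protocol
    name: Device
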