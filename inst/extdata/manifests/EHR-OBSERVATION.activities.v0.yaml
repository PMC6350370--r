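id: EHR-OBSERVATION.activities.v0
class: OBSERVATION
provenance: new
aliases:
  - indoor activities
items:
  - label: Data
    name: Duration
    value_kind: quantity
    units: min
    range:
      - 0.0
      - 1440.0
  - label: Data
    name: Description
    value_kind: text
  - label: Data
    name: Place
    value_kind: coded
    codes:
      - living room
      - restroom
      - bedroom
      - indoors
      - other
  - label: Protocol
    name: Device
    value_kind: coded
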