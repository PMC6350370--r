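id: EHR-OBSERVATION.outdoor_mobility_pattern.v0
class: OBSERVATION
provenance: new
aliases:
  - outdoor mobility pattern
items:
  - label: Data
    name: Distance
    value_kind: quantity
    units: km
    range:
      - 0.0
      - 50.0
  - label: Data
    name: Duration
    value_kind: quantity
    units: min
    range:
      - 0.0
      - 1440.0
  - label: Data
    name: Number of steps
    value_kind: quantity
    range:
      - 0.0
      - 40000.0
  - label: Data
    name: Radius
    value_kind: quantity
    units: km
    range:
      - 0.0
      - 50.0
  - label: Data
    name: Area
    value_kind: quantity
    units: km2
    range:
      - 0.0
      - 100.0
  - label: Data
    name: Average walk speed
    value_kind: quantity
    units: m/s
    range:
      - 0.0
      - 3.0
  - label: Data
    name: Total walk time
    value_kind: quantity
    units: min
    range:
      - 0.0
      - 600.0
  - label: Data
    name: Total stop time
    value_kind: quantity
    units: min
    range:
      - 0.0
      - 600.0
  - label: Data
    name: Total vehicle time
    value_kind: quantity
    units: min
    range:
      - 0.0
      - 600.0
  - label: Data
    name: Walk time percentage
    value_kind: quantity
    units: '%'
    range:
      - 0.0
      - 100.0
  - label: Data
    name: Vehicle time percentage
    value_kind: quantity
    units: '%'
    range:
      - 0.0
      - 100.0
  - label: Data
    name: Stop time percentage
    value_kind: quantity
    units: '%'
    range:
      - 0.0
      - 100.0
  - label: Data
    name: Number of tracks
    value_kind: quantity
    range:
      - 0.0
      - 50.0
  - label: Data
    name: Track average distance
    value_kind: quantity
    units: km
    range:
      - 0.0
      - 20.0
  - label: Data
    name: Track average duration
    value_kind: quantity
    units: min
    range:
      - 0.0
      - 300.0
  - label: Data
    name: Track maximum distance
    value_kind: quantity
    units: km
    range:
      - 0.0
      - 50.0
  - label: Data
    name: Track maximum duration
    value_kind: quantity
    units: min
    range:
      - 0.0
      - 600.0
  - label: Protocol
    name: Device
    value_kind: coded
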