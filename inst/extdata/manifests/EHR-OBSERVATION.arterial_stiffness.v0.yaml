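id: EHR-OBSERVATION.arterial_stiffness.v0
class: OBSERVATION
provenance: new
aliases:
  - arterial stiffness
items:
  - label: Data
    name: Pulse Amplification
    value_kind: quantity
    range:
      - 0.0
      - 3.0
  - label: Data
    name: Augmentation Index75
    value_kind: quantity
    units: '%'
    range:
      - -30.0
      - 60.0
  - label: Data
    name: Vascular Resistance
    value_kind: quantity
    units: mmHg.min/L
    range:
      - 10.0
      - 30.0
  - label: Data
    name: Cardiac Output
    value_kind: quantity
    units: L/min
    range:
      - 2.0
      - 8.0
  - label: Data
    name: Stroke Volume
    value_kind: quantity
    units: mL
    range:
      - 40.0
      - 120.0
  - label: Data
    name: Cardiac Index
    value_kind: quantity
    units: L/min/m2
    range:
      - 1.5
      - 5.0
  - label: Data
    name: Augmentation
    value_kind: quantity
    units: mmHg
    range:
      - -10.0
      - 40.0
  - label: Data
    name: Reflection Coefficient
    value_kind: quantity
    units: '%'
    range:
      - 0.0
      - 100.0
  - label: Data
    name: Pulse Wave Velocity
    value_kind: quantity
    units: m/s
    range:
      - 4.0
      - 20.0
  - label: Data
    name: Stiffness
    value_kind: quantity
    range:
      - 0.0
      - 30.0
  - label: Protocol
    name: Device
    value_kind: coded
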