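id: EHR-OBSERVATION.generalities_questionnaire.v0
class: OBSERVATION
provenance: new
aliases:
  - social interaction
items:
  - label: Data
    name: Phone Calls
    value_kind: score
    range:
      - 0.0
      - 100.0
  - label: Data
    name: Text Messages
    value_kind: score
    range:
      - 0.0
      - 200.0
  - label: Data
    name: Speaking Duration
    value_kind: quantity
    units: min
    range:
      - 0.0
      - 600.0
  - label: Data
    name: Video Conference Duration
    value_kind: quantity
    units: min
    range:
      - 0.0
      - 600.0
  - label: Data
    name: Living conditions
    value_kind: coded
    codes:
      - alone
      - with partner
      - with family
      - institution
  - label: Data
    name: Leisure activities
    value_kind: score
    range:
      - 0.0
      - 20.0
  - label: Data
    name: Leisure club
    value_kind: boolean
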