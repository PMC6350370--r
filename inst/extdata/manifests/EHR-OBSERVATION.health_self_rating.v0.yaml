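id: EHR-OBSERVATION.health_self_rating.v0
class: OBSERVATION
provenance: new
aliases:
  - health self rating
items:
  - label: Data
    name: Health status
    value_kind: score
    range:
      - 0.0
      - 10.0
  - label: Data
    name: Change
    value_kind: coded
    codes:
      - better
      - same
      - worse
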