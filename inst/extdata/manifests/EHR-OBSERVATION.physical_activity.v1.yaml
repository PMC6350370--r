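id: EHR-OBSERVATION.physical_activity.v1
class: OBSERVATION
provenance: reused
items:
  - label: Data
    name: Physical activity level
    value_kind: coded
    codes:
      - low
      - moderate
      - high
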