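id: EHR-OBSERVATION.visual_analogue_scale.v0
class: OBSERVATION
provenance: new
aliases:
  - visual analogue scale
  - wellness
items:
  - label: Data
    name: Score
    value_kind: score
    range:
      - 0.0
      - 10.0
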