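id: EHR-EVALUATION.tobacco_smoking_summary.v1
class: EVALUATION
provenance: reused
items:
  - label: Data
    name: Overall Status
    value_kind: coded
    codes:
      - never smoked
      - former smoker
      - current smoker
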