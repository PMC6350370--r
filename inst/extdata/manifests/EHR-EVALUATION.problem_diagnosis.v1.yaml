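id: EHR-EVALUATION.problem_diagnosis.v1
class: EVALUATION
provenance: reused
items:
  - label: Data
    name: Problem/Diagnosis name
    value_kind: text
  - label: Data
    name: Severity
    value_kind: coded
    codes:
      - mild
      - moderate
      - severe
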