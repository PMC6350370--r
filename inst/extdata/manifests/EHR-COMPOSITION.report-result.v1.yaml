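id: EHR-COMPOSITION.report-result.v1
class: COMPOSITION
provenance: reused
items:
  - label: Context
    name: Status
    value_kind: coded
    codes:
      - preliminary
      - final
  - label: Context
    name: Report identifier
    value_kind: text
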