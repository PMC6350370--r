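id: EHR-INSTRUCTION.notification.v0
class: INSTRUCTION
provenance: new
aliases:
  - notifications
items:
  - label: Data
    name: Category
    value_kind: coded
    codes:
      - alert
      - notification
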