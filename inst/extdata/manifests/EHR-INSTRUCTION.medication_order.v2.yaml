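id: EHR-INSTRUCTION.medication_order.v2
class: INSTRUCTION
provenance: reused
items:
  - label: Activities
    name: Order.Medication
    value_kind: text
  - label: Activities
    name: Order.Dose
    value_kind: text
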