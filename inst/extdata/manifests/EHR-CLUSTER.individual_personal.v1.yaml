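id: EHR-CLUSTER.individual_personal.v1
class: CLUSTER
provenance: reused
aliases:
  - patient identification
items:
  - label: Items
    name: Identifier
    value_kind: text
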