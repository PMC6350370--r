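id: EHR-CLUSTER.level_of_exertion.v1
class: CLUSTER
provenance: reused
items:
  - label: Items
    name: Exercise.Description
    value_kind: text
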