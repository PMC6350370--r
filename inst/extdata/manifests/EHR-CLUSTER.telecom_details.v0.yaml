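id: EHR-CLUSTER.telecom_details.v0
class: CLUSTER
provenance: reused
items:
  - label: Items
    name: Email Address
    value_kind: text
  - label: Items
    name: Telephone number
    value_kind: text
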