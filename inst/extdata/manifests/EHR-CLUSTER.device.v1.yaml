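id: EHR-CLUSTER.device.v1
class: CLUSTER
provenance: reused
aliases:
  - device
metadata:
  purpose: Describe a medical device used for a measurement
items:
  - label: Items
    name: Device name
    value_kind: text
  - label: Items
    name: Type
    value_kind: coded
    codes:
      - wearable
      - cuff
      - scale
      - other
  - label: Items
    name: Serial number
    value_kind: text
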