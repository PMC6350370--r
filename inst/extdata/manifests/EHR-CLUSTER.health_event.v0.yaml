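id: EHR-CLUSTER.health_event.v0
class: CLUSTER
provenance: new
aliases:
  - events
  - health event
metadata:
  note: Identifier normalized from the published form 'EHR-CLUSTER-health-event.v0'
items:
  - label: Items
    name: Event Name
    value_kind: text
  - label: Items
    name: Description
    value_kind: text
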