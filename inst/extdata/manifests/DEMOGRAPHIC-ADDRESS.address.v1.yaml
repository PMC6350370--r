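id: DEMOGRAPHIC-ADDRESS.address.v1
class: DEMOGRAPHIC
provenance: reused
aliases:
  - contact details
items:
  - label: Details
    name: Country identifier
    value_kind: coded
    codes:
      - GR
      - CY
      - FR
      - other
  - label: Details
    name: City
    value_kind: text
  - label: Details
    name: Street
    value_kind: text
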