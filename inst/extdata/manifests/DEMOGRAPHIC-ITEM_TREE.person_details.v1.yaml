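id: DEMOGRAPHIC-ITEM_TREE.person_details.v1
class: DEMOGRAPHIC
provenance: reused
aliases:
  - demographic details
  - personal details
items:
  - label: Data
    name: Birth date
    value_kind: date
  - label: Data
    name: Gender
    value_kind: coded
    codes:
      - female
      - male
      - other
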