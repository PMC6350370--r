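id: EHR-EVALUATION.clinical_synopsis.v1
class: EVALUATION
provenance: reused
aliases:
  - clinical synopsis
metadata:
  purpose: Narrative summary of a clinical encounter
  note: Exemplar evaluation archetype used in worked examples; not bound to a catalog
    parameter
items:
  - label: Data
    name: Synopsis
    value_kind: text
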