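id: EHR-OBSERVATION.cognitive_mood_sleep_questionnaire.v0
class: OBSERVATION
provenance: new
aliases:
  - cognitive state
items:
  - label: Data
    name: Memory complain
    value_kind: boolean
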