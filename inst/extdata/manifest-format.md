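# Archetype manifest format

One archetype per file, YAML. The manifest is the canonical on-disk form of
an archetype in this package: it captures the class/label/item structure an
archetype contributes to schema mapping, not the full authoring grammar of
ADL (which is out of scope).

## Keys

| key          | required | type                | meaning |
|--------------|----------|---------------------|---------|
| `id`         | yes      | string              | `<RM>-<TOKEN>.<concept>.v<N>`, e.g. `EHR-OBSERVATION.blood_pressure.v1`. The token must be a class name, or any RM-type token when the RM prefix is `DEMOGRAPHIC`. |
| `class`      | yes      | string              | One of `COMPOSITION`, `SECTION`, `OBSERVATION`, `EVALUATION`, `INSTRUCTION`, `ACTION`, `CLUSTER`, `DEMOGRAPHIC`; must agree with the id. |
| `items`      | yes      | list of item maps   | See below. |
| `provenance` | no       | string              | `reused` (default), `modified`, `new`. |
| `added_items`| iff modified | list of `{label, name}` | The subset of `items` added to the published original. |
| `aliases`    | no       | list of strings     | Alternative concept names for parameter matching. |
| `metadata`   | no       | map                 | Description/Attribution content (`author`, `purpose`, `use`, `note`, ...). Never itemized; routed to the metadata table. |

## Item maps

| key          | required | meaning |
|--------------|----------|---------|
| `label`      | yes      | Section label; must belong to the class's label set and may not be `Description` or `Attribution`. |
| `name`       | yes      | Item name, verbatim (spaces allowed; dotted names flatten items of a nested CLUSTER, e.g. `Exercise.Description`). `(label, name)` unique per archetype. |
| `value_kind` | no       | `quantity`, `text` (default), `coded`, `score`, `duration`, `date`, `boolean`. |
| `units`      | no       | Unit string (e.g. `mm[Hg]`); omitted when unitless. |
| `range`      | no       | `[min, max]` numeric bounds for quantity/score items; used by record validation hints and the synthetic generator. |
| `codes`      | no       | Allowed values for coded items. |

## Canonical serialization

`write_manifest()` emits keys in the fixed order `id`, `class`,
`provenance`, `aliases`, `metadata`, `items`, `added_items`, omitting empty
optional fields, with two-space indentation and indented sequences. The
serialization depends only on the archetype object, so a
write-read-write cycle is byte-stable.
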