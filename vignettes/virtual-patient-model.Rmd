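---
title: "Modelling an ageing-population virtual patient and storing it in a column-family layout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an ageing-population virtual patient and storing it in a column-family layout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archebase)
```

## The modelling problem

Frailty monitoring in older adults produces heterogeneous data: demographics
collected once, device measurements aggregated daily (heart rate,
respiration, blood pressure, mobility), questionnaire scores from
six-monthly comprehensive geriatric assessment (CGA) sessions, health
events, and clinician interventions. Two-level EHR modelling keeps this
tractable: a stable reference model is implemented in software, while the
clinical content is expressed as *archetypes* — formal, reusable models of
single clinical concepts (blood pressure, body weight, the Fried frailty
phenotype). `archebase` implements that representation for a frailty
virtual patient model (VPM) and a one-to-one mapping from archetypes onto a
wide-column (HBase-style) storage layout, together with a self-contained
column-family store so the whole pipeline runs and is testable without any
database service.

## Archetypes and the manifest dialect

An archetype belongs to one of eight classes (`COMPOSITION`, `SECTION`, the
ENTRY subclasses `OBSERVATION` / `EVALUATION` / `INSTRUCTION` / `ACTION`,
`CLUSTER`, `DEMOGRAPHIC`). Each class fixes a set of *labels* — the
sections under which items live. For observations the set is exactly
`State`, `Events`, `Data`, `Protocol`, `Description`, `Attribution`. The
label sets of the remaining classes are not fixed by any single published
enumeration; this package derives them from the labels its catalog
archetypes actually use (`Items` for clusters and sections, `Activities`
for instructions, `Details` for demographic addresses, `Context` for
compositions), a deliberately open design point: a manifest using a label
outside its class set is rejected at read time, so extending a class's
label set is an explicit, reviewable change to `archetype_classes()`.

Archetypes are authored in ADL in the wider ecosystem. ADL parsing is out
of scope here: the information this package consumes is the
class/label/item structure, which a small declarative YAML manifest
captures exactly (see `inst/extdata/manifest-format.md`). The manifest
writer is canonical — fixed key order, empty fields omitted — so
write/read/write cycles are byte-stable, which the tests assert.

Two invariants matter downstream:

* `Description` and `Attribution` never carry items. Their content
  (author, purpose, use) is archetype *metadata*, stored once per archetype
  in a separate metadata table — not repeated in every data row.
* `(label, item name)` pairs are unique per archetype and item names are
  compared case-sensitively after trimming, because they later become
  bit-exact column qualifiers.

A consequence of the second point: source tables for the catalog spell the
device item inconsistently (`device` vs `Device`); the fixtures normalise
to `Device` once so that qualifiers are stable.

## Reuse, modify, or create

Mapping a clinical parameter onto archetypes follows a three-case
procedure, implemented by `classify_provenance()`:

1. **Reuse** — an existing archetype models all required items of the
   parameter (unused extra items are simply not selected).
2. **Modify** — an archetype matches the parameter's concept but lacks
   items; `apply_modification()` adds the missing ones and records them as
   `added_items` (e.g. respiration extended with `State.Position` and
   `Protocol.Device`).
3. **New** — no archetype matches the concept; a new one is authored.

Concept matching is by the id's concept segment, case-insensitive with
punctuation folded, plus an alias list in the manifest ("heart rate" for
`pulse`). This was a genuinely open design choice: matching by item
overlap alone would conflate concepts that share generic item names
(`Total score` appears in five questionnaires), whereas concept/alias
matching keeps the decision clinical. Among concept matches the archetype
covering most required items wins; ties are broken lexicographically by id
and flagged `ambiguous` in the result rather than raised, so the function
is total and registry-order independent (a property the tests check by
permuting the registry).

## The packaged catalog

`load_default_catalog()` ships the frailty VPM: 22 parameters in four
categories (personal details; monitoring; events; interventions), bound to
50 registry archetypes — 20 reused (including one worked-example exemplar,
the clinical synopsis evaluation, which no parameter binds), 2 modified
(pulse, gaining `Data.Variability`; respiration, gaining `State.Position`
and `Protocol.Device`), and 28 newly developed, of which 19 appear in the
parameter tables and 9 are additional serious-game clusters. The game
identifiers `game2`–`game10` are synthetic: the archetypes' existence is
recorded but their names were never published, which their manifests note.
Two provenance judgements in the catalog index are themselves inferences
and are documented there: pulse is flagged modified because its
variability item is marked as added, and the health-event/notification
archetypes are flagged new (both are `v0` drafts and the table-listed new
count only reaches its recorded total with them). `catalog_counts()`
always reports the counts *computed* from the fixtures; nothing in the
package forces the reused count to any externally stated total.

## From archetypes to a column-family schema

The mapping has three steps, each a function:

1. `union_schema()` — **families**: the column families of a table are the
   union of the labels contributed by the mapped archetypes, minus
   `Description`/`Attribution`. Family order is first-seen and
   deterministic; permuting the input never changes the family set.
2. `map_archetype()` — **columns**: only *used* items produce columns; the
   family is the item's label and the qualifier is the item name verbatim,
   spaces included (wide-column stores accept arbitrary qualifier bytes).
   Items of a nested cluster flatten into the referencing entry with
   dotted qualifiers (`Order.Medication`), preserving one row per entry.
3. `build_rowkey()` — **rowkey**: `subject_date_archetype`, discussed
   below.

`partition_catalog()` routes the catalog into exactly two data tables —
`vpm_static` for personal details (rarely altered) and `vpm_dynamic` for
everything else (aggregated daily or per assessment) — plus
`vpm_archetype_meta` for the excluded metadata labels. Table names are
configurable; the defaults are package choices, since the layout itself
does not require particular names.

## Rowkey design

A dynamic rowkey is `subject id + "_" + YYYYMMDD + "_" + archetype id`.
The archetype id is part of the key because different archetypes share
item names: without it, a same-day blood-pressure and body-weight record
for one subject would collide on one rowkey and the later write would
silently overwrite the `Comment` and `Any event` cells of the earlier.
`build_rowkey(include_archetype = FALSE)` exists purely to demonstrate
this collision, and the tests reproduce it (four sample records yield
three keys without the archetype segment, four with it).

Parsing is unambiguous left-to-right because subject tokens exclude the
underscore separator (`[A-Za-z0-9-]+`), the date segment is exactly eight
digits, and the remainder — which may itself contain underscores — is the
archetype id. Static rows omit the date (`subject_archetype`); whether a
production deployment would key static rows this way is not externally
specified, so the choice is documented here as the package's own.
Dates are plain calendar dates with no timezone, validated against the
calendar (`20180230` is rejected): the format is fixed, its semantics were
an open point, and the simplest reading was chosen. Multiple same-day
measurements of one archetype collide *by design* — daily aggregation is
the data model — with last-write-wins visibility; raising `max_versions`
on the stores retains superseded cells instead.

## The column store

`column_table()` implements the minimal wide-column contract the mapping
needs: families fixed at creation, columns created on first write, cells
versioned (default 3 retained versions, matching common wide-column
defaults), point reads returning the latest value or the newest value
under a version bound, and scans over half-open `[start, stop)` rowkey
ranges in bytewise order. Bytewise comparisons are done against a
radix-sorted ordering rather than locale collation, so prefix scans
partition the keyspace by subject regardless of the session locale. The
store is deliberately single-writer and in-memory with a line-delimited
snapshot format; distribution, replication and concurrency are out of
scope. `cs_put()`/`cs_get()`/`cs_scan()` are S3 generics, so an adapter
for a live cluster can implement the same surface without touching
ingestion code. The store's correctness is established by equivalence
with an unindexed replay oracle (a log of all puts, queried naively) on
randomized workloads of a few thousand operations.

## Synthetic cohorts

`generate_records()` exists so ingestion, schema mapping and retrieval can
be exercised end-to-end with no external data. Its defaults emulate the
study conditions the catalog encodes: every daily (device) parameter once
per subject per day, every assessment parameter at sessions spaced
`assessment_interval_days = 182` days (six-monthly CGA), and one static
personal-details record per subject. Values are uniform draws inside the
physiologic ranges declared per item in the manifests (systolic 70–250
mm[Hg], weight 30–150 kg, GDS-15 score 0–15, ...); coded items draw from
their code lists. The generator models *structural* validity only — no
temporal autocorrelation, no frailty progression, no missingness, no
sensor noise — so passing round-trip tests demonstrates that the schema,
rowkeys and store faithfully carry any well-formed record stream, not that
the pipeline is robust to pathological real-world data.

Reproducibility uses counter-based substreams: subject *i*'s records
depend only on `(seed, i)`, so a subject's stream is identical whether the
cohort has one subject or a thousand, and equal seeds give byte-identical
record files. The record count has a closed form
(`expected_record_count()`), verified against actual generation.

One aliasing subtlety: two assessment parameters bind the same visual
analogue scale item, so same-session records for both would share a cell
coordinate and resolve by last-write-wins. The generator instantiates
each parameter through its first binding, which keeps its default stream
free of same-qualifier collisions; the round-trip property is therefore
asserted as exact record equality on generated streams.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as
comfortably beyond the structure they exercise: round-trip checks use a
cohort of 8 subjects over 9 days with the 7 daily parameters (512
records); store/oracle equivalence uses 2,000 randomized writes over 30
rowkeys with mixed point reads, version-bounded reads and range scans;
rowkey inversion and registry-permutation properties use dozens of random
cases under fixed seeds. Everything completes in about a minute on one
core. There are no tolerances anywhere: every compared quantity is a
count, a string, or an exact decimal string, so all assertions are exact.

## Known limitations

* The manifest dialect captures structure, not the full ADL constraint
  grammar (no cardinalities, no terminology bindings, no templates).
* Value validation is shallow by design: kind, code list, and (for the
  generator) range — not clinical plausibility or questionnaire scoring
  logic, which belong to the instruments, not the storage layer.
* The store is an emulator for development and testing; it honours the
  wide-column read/write contract but none of the operational concerns of
  a real cluster (regions, compaction, TTL, concurrency).
* Events are stored like any other record; alert delivery to clinicians is
  transport, out of scope.
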