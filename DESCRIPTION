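Package: archebase
Title: Archetype-Based Virtual Patient Models over a Wide-Column Store
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing an ageing-population virtual patient
    model as openEHR-style clinical archetypes and persisting it in a
    column-family (HBase-like) layout. Provides an archetype object model
    with a declarative text manifest format, the reuse/modify/create
    classification procedure used to map clinical parameters onto existing
    archetypes, a three-step archetype to column-family schema mapping with
    composite rowkeys (subject, date, archetype), a static/dynamic two-table
    partition, a self-contained in-memory column-family store with versioned
    cells and bytewise-ordered scans, and a seeded generator of synthetic
    frailty-monitoring records so ingestion and retrieval can be exercised
    with no external services. Ships the 22-parameter frailty virtual
    patient model catalog as manifest fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
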