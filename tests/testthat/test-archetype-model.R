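test_that("archetype ids parse into RM, class, concept and version", {
  p <- parse_archetype_id("EHR-OBSERVATION.blood_pressure.v1")
  expect_equal(p[c("rm", "klass", "concept", "version")],
               list(rm = "EHR", klass = "OBSERVATION",
                    concept = "blood_pressure", version = 1L))
  # concepts may contain dashes and dots-in-version only at the end
  expect_equal(parse_archetype_id("EHR-OBSERVATION.substance_use-alcohol.v1")$concept,
               "substance_use-alcohol")
  expect_equal(parse_archetype_id("EHR-OBSERVATION.gds-15_questionnaire.v0")$concept,
               "gds-15_questionnaire")
  # demographic RM-type tokens resolve to the DEMOGRAPHIC class
  expect_equal(parse_archetype_id("DEMOGRAPHIC-ITEM_TREE.person_details.v1")$klass,
               "DEMOGRAPHIC")
  expect_error(parse_archetype_id("not-an-id"), class = "abx_id_error")
  expect_error(parse_archetype_id("EHR-NOTACLASS.x.v1"),
               class = "abx_id_error")
})

test_that("observation label set is exact and metadata labels are universal", {
  cls <- archetype_classes()
  expect_setequal(cls$OBSERVATION,
                  c("State", "Events", "Data", "Protocol", "Description",
                    "Attribution"))
  for (k in names(cls)) {
    expect_gt(length(cls[[k]]), 0)
    expect_true(all(c("Description", "Attribution") %in% cls[[k]]))
  }
})

test_that("archetype invariants are enforced", {
  # items under metadata labels are forbidden
  expect_error(
    archetype("EHR-OBSERVATION.demo.v1",
              archetype_items("Description", "author")),
    class = "abx_invariant_error")
  # label must belong to the class
  expect_error(
    archetype("EHR-OBSERVATION.demo.v1", archetype_items("Details", "X")),
    class = "abx_invariant_error")
  # duplicate (label, name)
  expect_error(
    archetype("EHR-OBSERVATION.demo.v1",
              archetype_items("Data", c("Value", "Value"))),
    class = "abx_invariant_error")
  # added_items only for modified archetypes, and must be a subset
  expect_error(
    archetype("EHR-OBSERVATION.demo.v1", archetype_items("Data", "Value"),
              provenance = "modified"),
    class = "abx_invariant_error")
  expect_error(
    archetype("EHR-OBSERVATION.demo.v1", archetype_items("Data", "Value"),
              provenance = "modified",
              added_items = data.frame(label = "Data", name = "Other")),
    class = "abx_invariant_error")
})

test_that("manifest read/write round-trips and is byte-stable", {
  cat_ <- load_default_catalog()
  dir <- withr::local_tempdir()
  for (a in cat_$registry[c("EHR-OBSERVATION.blood_pressure.v1",
                            "EHR-OBSERVATION.respiration.v1",
                            "EHR-CLUSTER.red_wings_game.v0",
                            "DEMOGRAPHIC-ADDRESS.address.v1")]) {
    p1 <- file.path(dir, "a.yaml")
    p2 <- file.path(dir, "b.yaml")
    write_manifest(a, p1)
    b <- read_manifest(p1)
    expect_equal(b, a)
    write_manifest(b, p2)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)))
  }
})

test_that("malformed manifests fail with context", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.yaml")
  writeLines(c("id: EHR-OBSERVATION.demo.v1", "class: OBSERVATION",
               "items:", "  - label: Description", "    name: author"), p)
  expect_error(read_manifest(p), "Description", class = "abx_manifest_error")
  writeLines(c("id: EHR-OBSERVATION.demo.v1", "items: []"), p)
  expect_error(read_manifest(p), "class", class = "abx_manifest_error")
  writeLines(c("id: EHR-OBSERVATION.demo.v1", "class: EVALUATION",
               "items: []"), p)
  expect_error(read_manifest(p), "does not match",
               class = "abx_manifest_error")
  expect_error(read_manifest(file.path(dir, "absent.yaml")),
               class = "abx_manifest_error")
})

test_that("the manifest fixture for blood pressure matches its published shape", {
  man <- system.file("extdata", "manifests",
                     "EHR-OBSERVATION.blood_pressure.v1.yaml",
                     package = "archebase")
  a <- read_manifest(man)
  expect_equal(a$klass, "OBSERVATION")
  expect_true(all(c("Data.Systolic", "Data.Diastolic",
                    "Data.Pulse Pressure", "Events.Any event",
                    "Protocol.Device") %in% keys_of(a$items)))
  expect_equal(a$items$units[a$items$name == "Systolic"], "mm[Hg]")
})

test_that("classification reuses an archetype covering all required items", {
  cat_ <- load_default_catalog()
  req <- requirement_spec("Blood pressure",
                          c("Data.Systolic", "Data.Diastolic",
                            "Data.Pulse Pressure", "Events.Any event",
                            "Protocol.Device"))
  res <- classify_provenance(req, unname(cat_$registry))
  expect_equal(res$decision, "reuse")
  expect_equal(res$base$id, "EHR-OBSERVATION.blood_pressure.v1")
  expect_equal(nrow(res$missing), 0)
  expect_false(res$ambiguous)
})

test_that("classification flags concept matches lacking items as modify", {
  cat_ <- load_default_catalog()
  registry <- unname(cat_$registry)
  # recover the published respiration archetype (without the added fields)
  idx <- which(vapply(registry, function(a) a$id, character(1)) ==
                 "EHR-OBSERVATION.respiration.v1")
  registry[[idx]] <- strip_added(registry[[idx]])
  req <- requirement_spec("Respiration Rate",
                          c("Data.Rate", "Data.Depth", "State.Position",
                            "Events.Any event", "Protocol.Device"))
  res <- classify_provenance(req, registry)
  expect_equal(res$decision, "modify")
  expect_equal(res$base$id, "EHR-OBSERVATION.respiration.v1")
  expect_setequal(keys_of(res$missing),
                  c("State.Position", "Protocol.Device"))
})

test_that("classification reports new when no concept matches", {
  cat_ <- load_default_catalog()
  registry <- Filter(function(a) a$id != "EHR-OBSERVATION.arterial_stiffness.v0",
                     unname(cat_$registry))
  req <- requirement_spec("Arterial stiffness",
                          c("Data.Pulse Wave Velocity", "Data.Stiffness"))
  res <- classify_provenance(req, registry)
  expect_equal(res$decision, "new")
  expect_null(res$base)
  expect_equal(nrow(res$missing), 2)
})

test_that("classification is deterministic and registry-order independent", {
  cat_ <- load_default_catalog()
  registry <- unname(cat_$registry)
  idx <- which(vapply(registry, function(a) a$id, character(1)) ==
                 "EHR-OBSERVATION.respiration.v1")
  registry[[idx]] <- strip_added(registry[[idx]])
  reqs <- list(
    requirement_spec("Blood pressure", c("Data.Systolic", "Events.Any event")),
    requirement_spec("Respiration Rate", c("Data.Rate", "Protocol.Device")),
    requirement_spec("No such concept", "Data.X")
  )
  set.seed(42)
  for (req in reqs) {
    ref <- classify_provenance(req, registry)
    for (i in 1:5) {
      shuf <- registry[sample(seq_along(registry))]
      res <- classify_provenance(req, shuf)
      expect_equal(res$decision, ref$decision)
      expect_equal(res$base$id, ref$base$id)
      expect_equal(res$missing[order(res$missing$name), ],
                   ref$missing[order(ref$missing$name), ],
                   ignore_attr = TRUE)
    }
    # idempotence
    expect_equal(classify_provenance(req, registry), ref)
  }
})

test_that("apply_modification adds the missing items without touching the base", {
  cat_ <- load_default_catalog()
  base <- strip_added(cat_$registry[["EHR-OBSERVATION.respiration.v1"]])
  n_before <- nrow(base$items)
  mod <- apply_modification(base, c("State.Position", "Protocol.Device"))
  expect_equal(mod$provenance, "modified")
  expect_equal(nrow(mod$added_items), 2)
  expect_setequal(keys_of(mod$added_items),
                  c("State.Position", "Protocol.Device"))
  expect_true(all(keys_of(mod$added_items) %in% keys_of(mod$items)))
  expect_equal(nrow(base$items), n_before)  # base unchanged
  expect_equal(base$provenance, "reused")

  pulse <- strip_added(cat_$registry[["EHR-OBSERVATION.pulse.v1"]])
  mod2 <- apply_modification(pulse, "Data.Variability")
  expect_equal(keys_of(mod2$added_items), "Data.Variability")
})

test_that("modify decision is closed under apply_modification", {
  cat_ <- load_default_catalog()
  registry <- unname(cat_$registry)
  idx <- which(vapply(registry, function(a) a$id, character(1)) ==
                 "EHR-OBSERVATION.respiration.v1")
  registry[[idx]] <- strip_added(registry[[idx]])
  req <- requirement_spec("Respiration Rate",
                          c("Data.Rate", "State.Position",
                            "Protocol.Device"))
  res <- classify_provenance(req, registry)
  expect_equal(res$decision, "modify")
  mod <- apply_modification(res$base, res$missing)
  expect_true(all(keys_of(req$required_items) %in% keys_of(mod$items)))
})

test_that("apply_modification rejects empty and invalid additions", {
  a <- tiny_observation()
  expect_error(apply_modification(a, character(0)),
               class = "abx_modify_error")
  expect_error(apply_modification(a, "Data.Value"),
               class = "abx_modify_error")          # already present
  expect_error(apply_modification(a, "Details.X"),
               class = "abx_modify_error")          # label not in class
  expect_error(apply_modification(a, "Description.author"),
               class = "abx_modify_error")          # metadata label
})
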