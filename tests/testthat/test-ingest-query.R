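test_that("composite rowkeys render as subject_date_archetype", {
  expect_equal(
    build_rowkey("1001", "2018-03-12", "EHR-OBSERVATION.blood_pressure.v1"),
    "1001_20180312_EHR-OBSERVATION.blood_pressure.v1")
  # static rows omit the date
  expect_equal(
    build_rowkey("1001", NULL, "DEMOGRAPHIC-ITEM_TREE.person_details.v1"),
    "1001_DEMOGRAPHIC-ITEM_TREE.person_details.v1")
  expect_error(build_rowkey("10_01", "2018-03-12", "EHR-OBSERVATION.x.v1"),
               class = "abx_rowkey_error")
  expect_error(build_rowkey("1001", "2018-02-30", "EHR-OBSERVATION.x.v1"),
               class = "abx_rowkey_error")
  expect_error(build_rowkey("1001", "18-03-12", "EHR-OBSERVATION.x.v1"),
               class = "abx_rowkey_error")
})

test_that("rowkey parsing inverts rendering for random valid keys", {
  set.seed(7)
  cat_ <- load_default_catalog()
  ids <- names(cat_$registry)
  subjects <- random_subjects(40)
  dates <- format(as.Date("2016-01-01") + sample.int(2000, 40), "%Y%m%d")
  for (i in seq_along(subjects)) {
    aid <- sample(ids, 1)
    key <- build_rowkey(subjects[i], dates[i], aid)
    parsed <- parse_rowkey(key)
    expect_equal(parsed,
                 list(subject_id = subjects[i], date = dates[i],
                      archetype_id = aid))
    skey <- build_rowkey(subjects[i], NULL, aid)
    sparsed <- parse_rowkey(skey)
    expect_equal(sparsed$subject_id, subjects[i])
    expect_null(sparsed$date)
    expect_equal(sparsed$archetype_id, aid)
  }
})

test_that("distinct (subject, date, archetype) triples never collide", {
  set.seed(11)
  cat_ <- load_default_catalog()
  grid <- expand.grid(s = random_subjects(5),
                      d = c("20180312", "20180313"),
                      a = sample(names(cat_$registry), 5),
                      stringsAsFactors = FALSE)
  keys <- mapply(build_rowkey, grid$s, grid$d, grid$a)
  expect_equal(anyDuplicated(keys), 0)
})

test_that("dropping the archetype from the key reproduces the overwrite collision", {
  recs <- sample_records()
  with_arch <- vapply(recs, function(r) {
    build_rowkey(r$subject_id, r$date, r$archetype_id)
  }, character(1))
  without <- vapply(recs, function(r) {
    build_rowkey(r$subject_id, r$date, r$archetype_id,
                 include_archetype = FALSE)
  }, character(1))
  expect_equal(length(unique(with_arch)), 4)
  expect_equal(length(unique(without)), 3)  # exactly one collision
  expect_equal(sum(without == "1001_20180312"), 2)
})

test_that("the worked example ingests to the printed rowkeys and values", {
  cat_ <- load_default_catalog()
  stores <- vpm_stores(cat_)
  reports <- lapply(sample_records(), ingest, stores = stores)
  expect_true(all(vapply(reports, `[[`, character(1), "table") == "dynamic"))
  expect_setequal(
    vapply(reports, `[[`, character(1), "rowkey"),
    c("1001_20180312_EHR-OBSERVATION.blood_pressure.v1",
      "1001_20180312_EHR-OBSERVATION.body_weight.v2",
      "1001_20180422_EHR-EVALUATION.clinical_synopsis.v1",
      "1001_20180613_EHR-OBSERVATION.body_weight.v2"))
  expect_equal(nrow(unique(cs_scan(stores$dynamic)["rowkey"])), 4)

  bp <- fetch("1001", stores, date = "2018-03-12",
              archetype_id = "EHR-OBSERVATION.blood_pressure.v1")
  expect_length(bp, 1)
  expect_equal(bp[[1]]$values$Data$Systolic, "143.0")
  expect_equal(bp[[1]]$values$Events[["Any event"]], "Abnormal")
  bw <- fetch("1001", stores, date = "20180613",
              archetype_id = "EHR-OBSERVATION.body_weight.v2")
  expect_equal(bw[[1]]$values$Data$Weight, "92.3")
  expect_equal(bw[[1]]$values$Events[["Any event"]], "High weight gain")
})

test_that("personal-details records route to the static table without a date", {
  cat_ <- load_default_catalog()
  stores <- vpm_stores(cat_)
  r <- vpm_record("1001", NULL, "DEMOGRAPHIC-ITEM_TREE.person_details.v1",
                  list(Data = list(`Birth date` = "19340215",
                                   Gender = "female")))
  rep <- ingest(r, stores)
  expect_equal(rep$table, "static")
  expect_equal(rep$rowkey, "1001_DEMOGRAPHIC-ITEM_TREE.person_details.v1")
  expect_equal(nrow(cs_scan(stores$dynamic)), 0)
  got <- fetch("1001", stores)
  expect_length(got, 1)
  expect_equal(got[[1]]$values$Data$Gender, "female")
})

test_that("validation rejects undeclared items, bad values and bad units", {
  cat_ <- load_default_catalog()
  stores <- vpm_stores(cat_)
  # item declared in a different archetype
  r <- vpm_record("1001", "20180312", "EHR-OBSERVATION.body_weight.v2",
                  list(Data = list(Systolic = "143.0")))
  expect_error(ingest(r, stores), "Systolic", class = "abx_record_error")
  # unknown archetype
  r2 <- vpm_record("1001", "20180312", "EHR-OBSERVATION.unknown.v1",
                   list(Data = list(X = "1")))
  expect_error(ingest(r2, stores), class = "abx_record_error")
  # quantity that does not parse
  r3 <- vpm_record("1001", "20180312", "EHR-OBSERVATION.body_weight.v2",
                   list(Data = list(Weight = "heavy")))
  expect_error(ingest(r3, stores), class = "abx_record_error")
  # coded value outside the code list
  r4 <- vpm_record("1001", "20180312", "EHR-OBSERVATION.physical_activity.v1",
                   list(Data = list(`Physical activity level` = "extreme")))
  expect_error(ingest(r4, stores), class = "abx_record_error")
  # unit mismatch when the record states units
  r5 <- vpm_record("1001", "20180312", "EHR-OBSERVATION.body_weight.v2",
                   list(Data = list(Weight = "85.2")))
  r5$units <- list(Data = list(Weight = "lb"))
  expect_error(ingest(r5, stores), "unit", class = "abx_record_error")
})

test_that("same-coordinate rewrites obey last-write-wins", {
  cat_ <- load_default_catalog()
  stores <- vpm_stores(cat_)
  r1 <- vpm_record("1001", "20180312", "EHR-OBSERVATION.body_weight.v2",
                   list(Data = list(Weight = "85.2")))
  r2 <- vpm_record("1001", "20180312", "EHR-OBSERVATION.body_weight.v2",
                   list(Data = list(Weight = "86.0")))
  ingest(r1, stores); ingest(r2, stores)
  got <- fetch("1001", stores, date = "20180312")
  expect_length(got, 1)
  expect_equal(got[[1]]$values$Data$Weight, "86.0")
})

test_that("archetype metadata lands only in the metadata table", {
  cat_ <- load_default_catalog()
  stores <- vpm_stores(cat_)
  a <- cat_$registry[["EHR-OBSERVATION.blood_pressure.v1"]]
  n <- ingest_metadata(a, stores)
  expect_equal(n, length(a$metadata))
  expect_equal(cs_get(stores$metadata, a$id, "Attribution", "author"),
               "community clinical models program")
  expect_match(cs_get(stores$metadata, a$id, "Description", "purpose"),
               "arterial blood pressure")
  expect_equal(nrow(cs_scan(stores$static)), 0)
  expect_equal(nrow(cs_scan(stores$dynamic)), 0)
})

test_that("record files round-trip through the line-delimited format", {
  recs <- sample_records()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "records.jsonl")
  write_records(recs, path)
  back <- read_records(path)
  expect_equal(back, recs)
})
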