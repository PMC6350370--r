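# Composite rowkeys, record validation against archetypes, routing to the
# static/dynamic/metadata tables, and retrieval by prefix scan.
#
# Rowkey design: subject id + "_" + YYYYMMDD + "_" + archetype id for
# dynamic rows; the date segment is omitted for static rows. Subject ids
# exclude "_" so the rendered key parses unambiguously left to right. The
# archetype id is part of the key because different archetypes share item
# names: without it, same-day records for two archetypes would collide on
# one rowkey and overwrite each other's cells.

SUBJECT_RE <- "^[A-Za-z0-9-]+$"

render_date <- function(date) {
  if (inherits(date, "Date")) return(format(date, "%Y%m%d"))
  d <- as.character(date)
  if (grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", d)) d <- gsub("-", "", d)
  if (!grepl("^[0-9]{8}$", d)) {
    abx_stop(sprintf("invalid date '%s' (want YYYYMMDD or YYYY-MM-DD)",
                     date), "abx_rowkey_error")
  }
  parsed <- as.Date(d, format = "%Y%m%d")
  if (is.na(parsed) || format(parsed, "%Y%m%d") != d) {
    abx_stop(sprintf("impossible calendar date '%s'", date),
             "abx_rowkey_error")
  }
  d
}

#' Build a composite rowkey
#'
#' @param subject_id Subject identifier token (`[A-Za-z0-9-]+`; underscores
#'   are reserved as the key separator).
#' @param date Calendar date (`Date`, `"YYYY-MM-DD"` or `"YYYYMMDD"`), or
#'   `NULL` for a static (undated) row.
#' @param archetype_id Archetype identifier.
#' @param include_archetype Keep the archetype segment in the key. Setting
#'   this `FALSE` exists only to demonstrate the collision that motivates
#'   the composite design; production keys always include it.
#' @return The rendered rowkey string.
#' @export
#' @examples
#' build_rowkey("1001", "2018-03-12", "EHR-OBSERVATION.blood_pressure.v1")
build_rowkey <- function(subject_id, date, archetype_id,
                         include_archetype = TRUE) {
  if (!grepl(SUBJECT_RE, subject_id)) {
    abx_stop(sprintf("invalid subject id '%s' (allowed: [A-Za-z0-9-]+)",
                     subject_id), "abx_rowkey_error")
  }
  parts <- subject_id
  if (!is.null(date)) parts <- c(parts, render_date(date))
  if (include_archetype) {
    parse_archetype_id(archetype_id)
    parts <- c(parts, archetype_id)
  }
  paste(parts, collapse = "_")
}

#' Parse a composite rowkey
#'
#' Inverse of [build_rowkey()] for keys that include the archetype segment:
#' the text before the first underscore is the subject, an 8-digit second
#' segment is the date (absent for static keys), and the remainder — which
#' may itself contain underscores — is the archetype id.
#'
#' @param key Rendered rowkey.
#' @return List with `subject_id`, `date` (`"YYYYMMDD"` or `NULL`),
#'   `archetype_id`.
#' @export
parse_rowkey <- function(key) {
  parts <- strsplit(key, "_", fixed = TRUE)[[1]]
  if (length(parts) < 2L) {
    abx_stop(sprintf("cannot parse rowkey '%s'", key), "abx_rowkey_error")
  }
  subject <- parts[1L]
  rest <- parts[-1L]
  date <- NULL
  if (grepl("^[0-9]{8}$", rest[1L]) && length(rest) > 1L) {
    date <- rest[1L]
    rest <- rest[-1L]
  }
  list(subject_id = subject, date = date,
       archetype_id = paste(rest, collapse = "_"))
}

#' Construct a virtual-patient-model record
#'
#' One write unit: the values observed for one archetype, one subject, one
#' date (dateless for static personal-details records).
#'
#' @param subject_id Subject identifier token.
#' @param date Calendar date or `NULL` for static records.
#' @param archetype_id Archetype the values instantiate.
#' @param values Nested named list: `values[[label]][[item_name]] = value`
#'   (values are stored as text; quantities as decimal strings).
#' @return Object of class `vpm_record`.
#' @export
vpm_record <- function(subject_id, date, archetype_id, values) {
  if (!grepl(SUBJECT_RE, subject_id)) {
    abx_stop(sprintf("invalid subject id '%s'", subject_id),
             "abx_record_error")
  }
  if (!is.null(date)) date <- render_date(date)
  stopifnot(is.list(values), !is.null(names(values)))
  values <- lapply(values, function(v) {
    stopifnot(is.list(v) || !is.null(names(v)))
    lapply(as.list(v), as.character)
  })
  structure(list(subject_id = subject_id, date = date,
                 archetype_id = archetype_id, values = values),
            class = "vpm_record")
}

#' @export
print.vpm_record <- function(x, ...) {
  cat(sprintf("<vpm_record> %s %s %s: %d value(s)\n", x$subject_id,
              if (is.null(x$date)) "(static)" else x$date, x$archetype_id,
              sum(lengths(x$values))))
  invisible(x)
}

record_value_pairs <- function(record) {
  out <- list()
  for (label in names(record$values)) {
    vals <- record$values[[label]]
    for (nm in names(vals)) {
      out[[length(out) + 1L]] <- list(label = label, name = nm,
                                      value = vals[[nm]])
    }
  }
  out
}

value_parses <- function(value, kind, codes = character()) {
  switch(kind,
    quantity = ,
    duration = ,
    score = !is.na(suppressWarnings(as.numeric(value))),
    boolean = tolower(value) %in% c("true", "false"),
    date = !inherits(try(render_date(value), silent = TRUE), "try-error"),
    coded = nzchar(value) &&
      (length(codes) == 0L || value %in% codes),
    text = TRUE,
    FALSE
  )
}

#' Validate a record against its archetype
#'
#' Checks that the record's archetype is registered, every (label, item)
#' pair is declared by the archetype (and not under an excluded metadata
#' label), every value parses under the item's value kind, and units —
#' when supplied on the record — match the archetype's.
#'
#' @param record A [vpm_record()]; may carry an optional `units` element
#'   mirroring the shape of `values`.
#' @param cat A [vpm_catalog()].
#' @return The matched [archetype()], invisibly.
#' @export
validate_record <- function(record, cat) {
  stopifnot(inherits(record, "vpm_record"), inherits(cat, "vpm_catalog"))
  a <- cat$registry[[record$archetype_id]]
  if (is.null(a)) {
    abx_stop(sprintf("unknown archetype '%s'", record$archetype_id),
             "abx_record_error")
  }
  keys <- item_keys(a$items)
  for (pv in record_value_pairs(record)) {
    k <- paste(pv$label, pv$name, sep = ".")
    if (pv$label %in% EXCLUDED_LABELS) {
      abx_stop(sprintf("record carries metadata-label item '%s'", k),
               "abx_record_error")
    }
    idx <- match(k, keys)
    if (is.na(idx)) {
      abx_stop(sprintf("item '%s' not declared in %s", k, a$id),
               "abx_record_error")
    }
    it <- a$items[idx, ]
    if (!value_parses(pv$value, it$value_kind, it$codes[[1]])) {
      abx_stop(sprintf("value '%s' does not parse as %s for item '%s'",
                       pv$value, it$value_kind, k), "abx_record_error")
    }
    ru <- record$units[[pv$label]][[pv$name]]
    if (!is.null(ru) && nzchar(it$units) && !identical(ru, it$units)) {
      abx_stop(sprintf("unit mismatch for '%s': record '%s', archetype '%s'",
                       k, ru, it$units), "abx_record_error")
    }
  }
  invisible(a)
}

#' Create the table trio backing a catalog
#'
#' Builds the static, dynamic and metadata [column_table()]s from the
#' catalog's schema partition.
#'
#' @param cat A [vpm_catalog()].
#' @param table_names Passed to [partition_catalog()].
#' @param max_versions Cell versions retained (see [column_table()]); raise
#'   it to keep same-coordinate rewrites instead of silently superseding
#'   them.
#' @return Object of class `vpm_stores`: list with `static`, `dynamic`,
#'   `metadata` tables and the originating `catalog`.
#' @export
vpm_stores <- function(cat, table_names = c(static = "vpm_static",
                                            dynamic = "vpm_dynamic",
                                            metadata = "vpm_archetype_meta"),
                       max_versions = 3L) {
  schemas <- partition_catalog(cat, table_names)
  structure(
    list(static = column_table(schemas$static, max_versions),
         dynamic = column_table(schemas$dynamic, max_versions),
         metadata = column_table(schemas$metadata, max_versions),
         catalog = cat),
    class = "vpm_stores"
  )
}

route_record <- function(record, cat) {
  p <- parameter_for_archetype(cat, record$archetype_id)
  if (!is.null(p) && p$category == "personal_details") "static" else "dynamic"
}

#' Ingest one record
#'
#' Validates the record, routes it to the static table (personal-details
#' parameters, undated rowkey) or the dynamic table (everything else,
#' dated rowkey), and writes one cell per value under family = label,
#' qualifier = item name. Repeated same-day measurements of one archetype
#' share a rowkey by design (daily aggregation); visibility is
#' last-write-wins.
#'
#' @param record A [vpm_record()].
#' @param stores A [vpm_stores()].
#' @return Write report: list with `rowkey`, `table` (`"static"` or
#'   `"dynamic"`) and `cells_written`.
#' @export
ingest <- function(record, stores) {
  stopifnot(inherits(stores, "vpm_stores"))
  cat <- stores$catalog
  validate_record(record, cat)
  target <- route_record(record, cat)
  date <- if (target == "static") NULL else {
    if (is.null(record$date)) {
      abx_stop(sprintf(
        "record for '%s' routes to the dynamic table and needs a date",
        record$archetype_id), "abx_record_error")
    }
    record$date
  }
  rk <- build_rowkey(record$subject_id, date, record$archetype_id)
  n <- 0L
  for (pv in record_value_pairs(record)) {
    cs_put(stores[[target]], rk, pv$label, pv$name, pv$value)
    n <- n + 1L
  }
  list(rowkey = rk, table = target, cells_written = n)
}

#' Ingest archetype metadata
#'
#' Writes an archetype's descriptive metadata into the metadata table:
#' rowkey = archetype id, authoring keys (`author`, `translators`, ...)
#' under the `Attribution` family, everything else (`purpose`, `use`, ...)
#' under `Description`.
#'
#' @param a An [archetype()].
#' @param stores A [vpm_stores()].
#' @return Number of cells written, invisibly.
#' @export
ingest_metadata <- function(a, stores) {
  stopifnot(inherits(a, "archetype"), inherits(stores, "vpm_stores"))
  attribution_keys <- c("author", "translators", "contributors", "origin")
  n <- 0L
  for (key in names(a$metadata)) {
    fam <- if (key %in% attribution_keys) "Attribution" else "Description"
    cs_put(stores$metadata, a$id, fam, key,
           paste(as.character(a$metadata[[key]]), collapse = "; "))
    n <- n + 1L
  }
  invisible(n)
}

prefix_stop <- function(prefix) {
  # smallest string strictly greater than every string with this prefix:
  # bump the final byte (all key alphabets here are ASCII below 0x7F)
  raw <- charToRaw(prefix)
  raw[length(raw)] <- as.raw(as.integer(raw[length(raw)]) + 1L)
  rawToChar(raw)
}

#' Fetch records for a subject
#'
#' Reconstructs records from cells via a bytewise prefix scan over the
#' static and dynamic tables, optionally narrowed by date and/or archetype.
#' On the written subset this is the inverse of [ingest()].
#'
#' @param subject_id Subject identifier token.
#' @param stores A [vpm_stores()].
#' @param date Optional date filter.
#' @param archetype_id Optional archetype filter.
#' @return List of [vpm_record()]s in rowkey order (static rows first).
#' @export
fetch <- function(subject_id, stores, date = NULL, archetype_id = NULL) {
  stopifnot(inherits(stores, "vpm_stores"))
  if (!grepl(SUBJECT_RE, subject_id)) {
    abx_stop(sprintf("invalid subject id '%s'", subject_id),
             "abx_record_error")
  }
  if (!is.null(date)) date <- render_date(date)
  start <- paste0(subject_id, "_")
  stop_ <- prefix_stop(start)
  cells <- rbind(cs_scan(stores$static, start, stop_),
                 cs_scan(stores$dynamic, start, stop_))
  if (nrow(cells) == 0L) return(list())
  out <- list()
  for (rk in unique(cells$rowkey)) {
    parsed <- parse_rowkey(rk)
    if (!is.null(date) && !identical(parsed$date, date)) next
    if (!is.null(archetype_id) && parsed$archetype_id != archetype_id) next
    sub <- cells[cells$rowkey == rk, , drop = FALSE]
    values <- list()
    for (i in seq_len(nrow(sub))) {
      values[[sub$family[i]]][[sub$qualifier[i]]] <- sub$value[i]
    }
    out[[length(out) + 1L]] <- vpm_record(parsed$subject_id, parsed$date,
                                          parsed$archetype_id, values)
  }
  out
}

# --- record file format: line-delimited JSON --------------------------------

#' Read records from a line-delimited JSON file
#'
#' One record per line: object with keys `subject_id`, `archetype_id`,
#' `values` (nested label -> item -> value map) and optionally `date`
#' (`"YYYYMMDD"`; absent for static records).
#'
#' @param path Input file.
#' @return List of [vpm_record()]s.
#' @export
read_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    doc <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    vpm_record(doc$subject_id, doc$date, doc$archetype_id, doc$values)
  })
}

#' Write records to a line-delimited JSON file
#'
#' @param records List of [vpm_record()]s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in records) {
    doc <- list(subject_id = r$subject_id)
    if (!is.null(r$date)) doc$date <- r$date
    doc$archetype_id <- r$archetype_id
    doc$values <- r$values
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' The worked ingestion example records
#'
#' The four sample clinical entries used throughout the documentation to
#' demonstrate the mapping: two body-weight observations, one blood-pressure
#' observation and one clinical-synopsis evaluation for subject 1001 in
#' spring 2018.
#'
#' @return List of four [vpm_record()]s.
#' @export
sample_records <- function() {
  list(
    vpm_record("1001", "20180312", "EHR-OBSERVATION.blood_pressure.v1",
               list(Data = list(Systolic = "143.0", Comment = "High BP"),
                    Events = list(`Any event` = "Abnormal"))),
    vpm_record("1001", "20180312", "EHR-OBSERVATION.body_weight.v2",
               list(Data = list(Weight = "85.2", Comment = "Normal"),
                    Events = list(`Any event` = "No"))),
    vpm_record("1001", "20180422", "EHR-EVALUATION.clinical_synopsis.v1",
               list(Data = list(Synopsis = "Synopsis text"))),
    vpm_record("1001", "20180613", "EHR-OBSERVATION.body_weight.v2",
               list(Data = list(Weight = "92.3", Comment = "Obesity"),
                    Events = list(`Any event` = "High weight gain")))
  )
}
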