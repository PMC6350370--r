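# Declarative text manifest format for archetypes (YAML dialect).
#
# One archetype per file. Required keys: id, class, items; optional:
# provenance, aliases, metadata, added_items. The format is documented in
# inst/extdata/manifest-format.md and serves as the canonical on-disk form
# in place of ADL, whose grammar is out of scope for this package.

MANIFEST_REQUIRED_KEYS <- c("id", "class", "items")
MANIFEST_KEYS <- c("id", "class", "provenance", "aliases", "metadata",
                   "items", "added_items")

#' Read an archetype manifest
#'
#' Parses and validates one archetype manifest file. Every archetype
#' invariant is enforced on read: the id must parse and agree with the
#' declared class, item labels must belong to the class's label set, no item
#' may sit under `Description`/`Attribution` (that content belongs in
#' `metadata`), and `(label, name)` pairs must be unique.
#'
#' @param path Path to a manifest file.
#' @return An [archetype()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abx_stop(sprintf("manifest not found: %s", path), "abx_manifest_error")
  }
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      abx_stop(sprintf("cannot parse manifest %s: %s",
                       path, conditionMessage(e)), "abx_manifest_error")
    }
  )
  miss <- setdiff(MANIFEST_REQUIRED_KEYS, names(doc))
  if (length(miss)) {
    abx_stop(sprintf("manifest %s lacks required key(s): %s",
                     path, paste(miss, collapse = ", ")),
             "abx_manifest_error")
  }
  unknown <- setdiff(names(doc), MANIFEST_KEYS)
  if (length(unknown)) {
    abx_stop(sprintf("manifest %s has unknown key(s): %s",
                     path, paste(unknown, collapse = ", ")),
             "abx_manifest_error")
  }
  items <- manifest_items_to_df(doc$items, path)
  added <- if (is.null(doc$added_items)) NULL else {
    ad <- manifest_items_to_df(doc$added_items, path, pairs_only = TRUE)
    ad[, c("label", "name")]
  }
  a <- tryCatch(
    archetype(
      id = doc$id,
      items = items,
      metadata = if (is.null(doc$metadata)) list() else doc$metadata,
      provenance = if (is.null(doc$provenance)) "reused" else doc$provenance,
      added_items = added,
      aliases = if (is.null(doc$aliases)) character() else
        unlist(doc$aliases)
    ),
    archebase_error = function(e) {
      abx_stop(sprintf("invalid manifest %s: %s", path, conditionMessage(e)),
               "abx_manifest_error")
    }
  )
  if (a$klass != doc$class) {
    abx_stop(sprintf(
      "manifest %s: declared class '%s' does not match id class '%s'",
      path, doc$class, a$klass), "abx_manifest_error")
  }
  a
}

manifest_items_to_df <- function(items, path, pairs_only = FALSE) {
  if (is.null(items) || length(items) == 0L) return(empty_items())
  rows <- lapply(seq_along(items), function(i) {
    it <- items[[i]]
    if (is.null(it$label) || is.null(it$name)) {
      abx_stop(sprintf("manifest %s: item %d lacks label or name",
                       path, i), "abx_manifest_error")
    }
    if (pairs_only) {
      return(archetype_items(it$label, it$name))
    }
    rng <- it$range
    archetype_items(
      label = it$label, name = it$name,
      value_kind = if (is.null(it$value_kind)) "text" else it$value_kind,
      units = if (is.null(it$units)) "" else it$units,
      range_min = if (is.null(rng)) NA_real_ else as.numeric(rng[[1]]),
      range_max = if (is.null(rng)) NA_real_ else as.numeric(rng[[2]]),
      codes = if (is.null(it$codes)) NULL else list(unlist(it$codes))
    )
  })
  do.call(rbind, rows)
}

#' Write an archetype manifest
#'
#' Serializes an archetype to its canonical manifest form. The serialization
#' is a pure function of the archetype (fixed key order, empty fields
#' omitted), so write-read-write round trips are byte-stable.
#'
#' @param a An [archetype()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(a, path) {
  stopifnot(inherits(a, "archetype"))
  doc <- list(id = a$id, class = a$klass, provenance = a$provenance)
  if (length(a$aliases)) doc$aliases <- as.list(a$aliases)
  if (length(a$metadata)) doc$metadata <- a$metadata
  doc$items <- lapply(seq_len(nrow(a$items)), function(i) {
    it <- a$items[i, ]
    out <- list(label = it$label, name = it$name, value_kind = it$value_kind)
    if (nzchar(it$units)) out$units <- it$units
    if (!is.na(it$range_min) || !is.na(it$range_max)) {
      out$range <- list(it$range_min, it$range_max)
    }
    cds <- it$codes[[1]]
    if (length(cds)) out$codes <- as.list(cds)
    out
  })
  if (nrow(a$added_items)) {
    doc$added_items <- lapply(seq_len(nrow(a$added_items)), function(i) {
      list(label = a$added_items$label[i], name = a$added_items$name[i])
    })
  }
  txt <- yaml::as.yaml(doc, indent = 2, indent.mapping.sequence = TRUE)
  writeLines(txt, path, sep = "")
  invisible(path)
}
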