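# Object model for clinical archetypes and the reuse/modify/create procedure.

#' Archetype classes and their label sets
#'
#' The archetype classes of the two-level EHR model and, for each class, the
#' ordered set of labels its items may carry. Labels are the top-level
#' sections of an archetype (e.g. `Data`, `State`, `Events`, `Protocol`);
#' `Description` and `Attribution` hold authoring metadata common to every
#' class and never carry clinical items.
#'
#' @return Named list mapping class token to a character vector of allowed
#'   labels.
#' @export
#' @examples
#' archetype_classes()$OBSERVATION
archetype_classes <- function() {
  meta <- c("Description", "Attribution")
  list(
    COMPOSITION = c("Context", "Content", meta),
    SECTION     = c("Items", meta),
    OBSERVATION = c("State", "Events", "Data", "Protocol", meta),
    EVALUATION  = c("Data", "Protocol", meta),
    INSTRUCTION = c("Activities", "Data", "Protocol", meta),
    ACTION      = c("Data", "Protocol", meta),
    CLUSTER     = c("Items", "Data", meta),
    DEMOGRAPHIC = c("Data", "Details", "Items", meta)
  )
}

# labels that hold archetype metadata, never stored per record
EXCLUDED_LABELS <- c("Description", "Attribution")

VALUE_KINDS <- c("quantity", "text", "coded", "score", "duration", "date",
                 "boolean")

PROVENANCE_LEVELS <- c("reused", "modified", "new")

abx_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "archebase_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Parse an archetype identifier
#'
#' Identifiers have the form `<RM>-<TOKEN>.<concept>.v<N>`, e.g.
#' `EHR-OBSERVATION.blood_pressure.v1`. The class token normally follows the
#' reference-model prefix; demographic archetypes instead carry the RM-type
#' after a `DEMOGRAPHIC` prefix (e.g. `DEMOGRAPHIC-ADDRESS.address.v1`) and
#' resolve to class `DEMOGRAPHIC`.
#'
#' @param id Archetype identifier string.
#' @return List with `rm`, `token`, `klass`, `concept`, `version`.
#' @export
#' @examples
#' parse_archetype_id("EHR-OBSERVATION.blood_pressure.v1")
parse_archetype_id <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  m <- regmatches(id, regexec(
    "^([A-Za-z0-9]+)-([A-Za-z0-9_]+)\\.(.+)\\.v([0-9]+)$", id))[[1]]
  if (length(m) == 0L) {
    abx_stop(sprintf("invalid archetype id: '%s'", id), "abx_id_error")
  }
  rm_prefix <- m[2]; token <- m[3]
  klass <- if (token %in% names(archetype_classes())) {
    token
  } else if (rm_prefix == "DEMOGRAPHIC") {
    "DEMOGRAPHIC"
  } else {
    abx_stop(sprintf("unknown archetype class token '%s' in id '%s'",
                     token, id), "abx_id_error")
  }
  list(rm = rm_prefix, token = token, klass = klass,
       concept = m[4], version = as.integer(m[5]))
}

#' Build an archetype item table
#'
#' @param label Label token (section) for each item.
#' @param name Item name, verbatim; may contain spaces and dots (dotted names
#'   flatten items of a nested CLUSTER, e.g. `"Exercise.Description"`).
#' @param value_kind One of `r paste(VALUE_KINDS, collapse = ", ")`.
#' @param units Unit string, `""` when unitless.
#' @param range_min,range_max Optional numeric bounds for quantity/score
#'   items; used by the synthetic generator and by record validation.
#' @param codes Optional list of allowed code strings for coded items.
#' @return A data.frame with one row per item.
#' @export
archetype_items <- function(label, name, value_kind = "text", units = "",
                            range_min = NA_real_, range_max = NA_real_,
                            codes = NULL) {
  n <- length(name)
  df <- data.frame(
    label = rep_len(as.character(label), n),
    name = trimws(as.character(name)),
    value_kind = rep_len(as.character(value_kind), n),
    units = rep_len(as.character(units), n),
    range_min = rep_len(as.numeric(range_min), n),
    range_max = rep_len(as.numeric(range_max), n),
    stringsAsFactors = FALSE
  )
  df$codes <- if (is.null(codes)) rep(list(character()), n) else {
    if (!is.list(codes)) codes <- list(codes)
    rep_len(lapply(codes, as.character), n)
  }
  df
}

empty_items <- function() archetype_items(character(), character())[0, ]

#' Construct and validate an archetype
#'
#' @param id Archetype identifier (see [parse_archetype_id()]).
#' @param items Item table from [archetype_items()] (rows may be concatenated
#'   with `rbind`).
#' @param metadata Named list of descriptive keys (author, purpose, use, ...);
#'   this is the `Description`/`Attribution` content and is kept out of the
#'   item table by design.
#' @param provenance One of `"reused"`, `"modified"`, `"new"`.
#' @param added_items For modified archetypes, the subset of `items` that was
#'   added to the published original (data.frame with `label`, `name`).
#' @param aliases Character vector of alternative concept names used when
#'   matching clinical parameters to archetypes.
#' @return An object of class `archetype`.
#' @export
#' @examples
#' a <- archetype(
#'   "EHR-OBSERVATION.demo.v1",
#'   rbind(archetype_items("Data", "Value", "quantity", "kg", 0, 100),
#'         archetype_items("Events", "Any event")))
#' a$klass
archetype <- function(id, items, metadata = list(), provenance = "reused",
                      added_items = NULL, aliases = character()) {
  parsed <- parse_archetype_id(id)
  if (is.null(items) || nrow(items) == 0L) {
    items <- empty_items()
  }
  if (is.null(added_items)) added_items <- empty_items()[, c("label", "name")]
  a <- structure(
    list(
      id = id, rm = parsed$rm, klass = parsed$klass,
      concept = parsed$concept, version = parsed$version,
      items = items, metadata = metadata,
      provenance = provenance,
      added_items = added_items[, c("label", "name"), drop = FALSE],
      aliases = as.character(aliases)
    ),
    class = "archetype"
  )
  validate_archetype(a)
  a
}

#' @export
print.archetype <- function(x, ...) {
  cat(sprintf("<archetype> %s [%s, %s]\n", x$id, x$klass, x$provenance))
  if (nrow(x$items)) {
    cat(sprintf("  %d items: %s\n", nrow(x$items),
                paste(utils::head(item_keys(x$items), 6L), collapse = ", ")))
  }
  if (nrow(x$added_items)) {
    cat("  added:", paste(item_keys(x$added_items), collapse = ", "), "\n")
  }
  invisible(x)
}

item_keys <- function(items) paste(items$label, items$name, sep = ".")

validate_archetype <- function(a) {
  allowed <- archetype_classes()[[a$klass]]
  if (!a$provenance %in% PROVENANCE_LEVELS) {
    abx_stop(sprintf("provenance must be one of %s (got '%s')",
                     paste(PROVENANCE_LEVELS, collapse = "/"), a$provenance),
             "abx_invariant_error")
  }
  it <- a$items
  if (nrow(it)) {
    if (any(!nzchar(trimws(it$name)))) {
      abx_stop("item name must be non-empty", "abx_invariant_error")
    }
    bad <- setdiff(unique(it$label), allowed)
    if (length(bad)) {
      abx_stop(sprintf("label(s) %s not allowed for class %s",
                       paste(sQuote(bad), collapse = ", "), a$klass),
               "abx_invariant_error")
    }
    excl <- intersect(unique(it$label), EXCLUDED_LABELS)
    if (length(excl)) {
      abx_stop(sprintf(
        "items under label(s) %s are forbidden: that content is archetype metadata",
        paste(sQuote(excl), collapse = ", ")), "abx_invariant_error")
    }
    if (anyDuplicated(item_keys(it))) {
      dup <- item_keys(it)[duplicated(item_keys(it))]
      abx_stop(sprintf("duplicate item(s): %s", paste(dup, collapse = ", ")),
               "abx_invariant_error")
    }
    if (any(!it$value_kind %in% VALUE_KINDS)) {
      abx_stop(sprintf("value_kind must be one of %s",
                       paste(VALUE_KINDS, collapse = ", ")),
               "abx_invariant_error")
    }
  }
  ad <- a$added_items
  if (nrow(ad) && !all(item_keys(ad) %in% item_keys(it))) {
    abx_stop("added_items must be a subset of items", "abx_invariant_error")
  }
  if (a$provenance == "modified" && nrow(ad) == 0L) {
    abx_stop("a modified archetype must declare its added_items",
             "abx_invariant_error")
  }
  if (a$provenance != "modified" && nrow(ad) > 0L) {
    abx_stop("added_items are only meaningful for provenance 'modified'",
             "abx_invariant_error")
  }
  invisible(a)
}

#' Split "Label.Item name" strings into (label, name) pairs
#'
#' Labels never contain dots, so the split is on the first dot only;
#' everything after it is the item name verbatim (which may itself contain
#' dots, e.g. `"Items.Exercise.Description"`).
#'
#' @param x Character vector of `"Label.Name"` strings, or a data.frame that
#'   already has `label` and `name` columns (returned as-is).
#' @return data.frame with columns `label`, `name`.
#' @export
item_pairs <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("label", "name") %in% names(x)))
    out <- x[, intersect(c("label", "name", "value_kind", "units"), names(x)),
             drop = FALSE]
    out$name <- trimws(out$name)
    return(out)
  }
  x <- as.character(x)
  bad <- !grepl(".", x, fixed = TRUE)
  if (any(bad)) {
    abx_stop(sprintf("not of the form 'Label.Name': %s",
                     paste(sQuote(x[bad]), collapse = ", ")),
             "abx_item_error")
  }
  data.frame(
    label = sub("\\..*$", "", x),
    name = trimws(sub("^[^.]*\\.", "", x)),
    stringsAsFactors = FALSE
  )
}

#' Requirement specification for one clinical parameter
#'
#' A requirement names a clinically meaningful parameter (e.g. "Blood
#' pressure") and lists the (label, item) pairs the use case must be able to
#' store. Requirements drive [classify_provenance()].
#'
#' @param parameter_name Parameter name.
#' @param required_items Items, as `"Label.Name"` strings or a data.frame
#'   with `label`/`name` columns. Must be non-empty.
#' @return Object of class `requirement_spec`.
#' @export
requirement_spec <- function(parameter_name, required_items) {
  ri <- item_pairs(required_items)
  if (nrow(ri) == 0L) {
    abx_stop("required_items must be non-empty", "abx_invariant_error")
  }
  structure(list(parameter_name = parameter_name,
                 required_items = ri[, c("label", "name")]),
            class = "requirement_spec")
}

normalize_concept <- function(x) {
  gsub("(^_)|(_$)", "", gsub("[^a-z0-9]+", "_", tolower(trimws(x))))
}

concept_matches <- function(a, parameter_name) {
  normalize_concept(parameter_name) == normalize_concept(a$concept) ||
    tolower(trimws(parameter_name)) %in% tolower(trimws(a$aliases))
}

#' Classify a parameter requirement against an archetype registry
#'
#' Implements the three-case procedure for adopting archetypes: an existing
#' archetype is *reused* when all required items of the parameter are already
#' modelled in it; it is *modified* when it matches the parameter's concept
#' but lacks one or more items (the missing ones are returned so
#' [apply_modification()] can add them); a *new* archetype is needed when no
#' registry archetype matches the concept at all.
#'
#' Concept matching compares the requirement's parameter name against each
#' archetype's id concept segment (case-insensitively, punctuation folded to
#' underscores) and against its declared aliases. Among concept matches the
#' archetype covering the most required items wins; ties are broken by
#' lexicographic id and flagged `ambiguous` in the result rather than raised.
#'
#' @param req A [requirement_spec()].
#' @param registry List of [archetype()] objects with unique ids.
#' @return List with `decision` (`"reuse"`, `"modify"` or `"new"`), `base`
#'   (the matched archetype or `NULL`), `missing` (data.frame of label/name
#'   pairs the base lacks; all required items when `decision == "new"`), and
#'   `ambiguous` (logical).
#' @export
classify_provenance <- function(req, registry) {
  stopifnot(inherits(req, "requirement_spec"))
  ids <- vapply(registry, function(a) a$id, character(1))
  if (anyDuplicated(ids)) {
    abx_stop("registry archetype ids must be unique", "abx_invariant_error")
  }
  cand <- registry[vapply(registry, concept_matches, logical(1),
                          parameter_name = req$parameter_name)]
  need <- item_keys(req$required_items)
  if (length(cand) == 0L) {
    return(list(decision = "new", base = NULL,
                missing = req$required_items, ambiguous = FALSE))
  }
  cover <- vapply(cand, function(a) sum(need %in% item_keys(a$items)),
                  integer(1))
  best_cover <- max(cover)
  top <- cand[cover == best_cover]
  top_ids <- vapply(top, function(a) a$id, character(1))
  base <- top[[order(top_ids)[1L]]]
  missing <- req$required_items[!need %in% item_keys(base$items), ,
                                drop = FALSE]
  rownames(missing) <- NULL
  list(
    decision = if (nrow(missing) == 0L) "reuse" else "modify",
    base = base,
    missing = missing,
    ambiguous = length(top) > 1L
  )
}

#' Add missing items to an existing archetype
#'
#' Produces the modified-and-reused form of an archetype: the published item
#' set plus the items a use case needs but the original lacks (e.g. extending
#' the respiration archetype with `State.Position` and `Protocol.Device`).
#' The base object is not altered.
#'
#' @param base Archetype to extend.
#' @param missing Items to add: `"Label.Name"` strings or a data.frame with
#'   `label`/`name` and optionally `value_kind`/`units` columns (defaults
#'   `"text"` / `""`). Must be non-empty and disjoint from `base$items`.
#' @return A new archetype with `provenance = "modified"` and
#'   `added_items = missing`.
#' @export
apply_modification <- function(base, missing) {
  stopifnot(inherits(base, "archetype"))
  add <- item_pairs(missing)
  if (nrow(add) == 0L) {
    abx_stop("nothing to add: 'missing' must be non-empty", "abx_modify_error")
  }
  clash <- item_keys(add) %in% item_keys(base$items)
  if (any(clash)) {
    abx_stop(sprintf("item(s) already present in %s: %s", base$id,
                     paste(item_keys(add)[clash], collapse = ", ")),
             "abx_modify_error")
  }
  allowed <- setdiff(archetype_classes()[[base$klass]], EXCLUDED_LABELS)
  bad <- setdiff(unique(add$label), allowed)
  if (length(bad)) {
    abx_stop(sprintf("label(s) %s not allowed for class %s",
                     paste(sQuote(bad), collapse = ", "), base$klass),
             "abx_modify_error")
  }
  if (is.null(add$value_kind)) add$value_kind <- "text"
  if (is.null(add$units)) add$units <- ""
  new_rows <- archetype_items(add$label, add$name, add$value_kind, add$units)
  archetype(
    id = base$id,
    items = rbind(base$items, new_rows),
    metadata = base$metadata,
    provenance = "modified",
    added_items = add[, c("label", "name")],
    aliases = base$aliases
  )
}
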