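# Three-step mapping from archetypes to wide-column table schemas:
#   1. column families  <- the labels of the archetype classes in use,
#      minus Description/Attribution (archetype metadata, stored apart);
#   2. columns          <- one per *used* archetype item, family = label,
#      qualifier = item name verbatim;
#   3. rowkey           <- subject id + date + archetype id (see ingest).

TABLE_ROLES <- c("static", "dynamic", "metadata")

#' Wide-column table schema
#'
#' Only column families are fixed by a wide-column table schema; columns are
#' created dynamically at write time. `Description` and `Attribution` are
#' never families of a data (static/dynamic) table — that content lives in
#' the metadata table.
#'
#' @param name Table name token.
#' @param families Character vector of family tokens (label names verbatim),
#'   in schema order.
#' @param role One of `"static"`, `"dynamic"`, `"metadata"`.
#' @return Object of class `table_schema`.
#' @export
table_schema <- function(name, families, role = "dynamic") {
  stopifnot(role %in% TABLE_ROLES)
  families <- unique(as.character(families))
  if (role != "metadata") {
    bad <- intersect(families, EXCLUDED_LABELS)
    if (length(bad)) {
      abx_stop(sprintf("family(ies) %s not allowed in a %s table",
                       paste(sQuote(bad), collapse = ", "), role),
               "abx_schema_error")
    }
  }
  structure(list(name = name, families = families, role = role),
            class = "table_schema")
}

#' @export
print.table_schema <- function(x, ...) {
  cat(sprintf("<table_schema> %s (%s): %s\n", x$name, x$role,
              paste(x$families, collapse = ", ")))
  invisible(x)
}

#' Map one archetype onto schema columns
#'
#' Step 2 of the mapping: only the items a use case actually stores become
#' columns — one column per used item, with the item's label as the column
#' family and the item name, verbatim, as the qualifier. Items under the
#' excluded metadata labels can never produce columns.
#'
#' @param a An [archetype()].
#' @param used_items Non-empty subset of `a$items`, as `"Label.Name"`
#'   strings or a label/name data.frame.
#' @return Object of class `schema_fragment` with `archetype_id` and
#'   `columns` (data.frame `family`, `qualifier`, sorted bytewise).
#' @export
#' @examples
#' bw <- archetype("EHR-OBSERVATION.body_weight.v2",
#'   rbind(archetype_items("Data", c("Weight", "Comment")),
#'         archetype_items("Events", "Any event")))
#' map_archetype(bw, c("Data.Weight", "Events.Any event"))
map_archetype <- function(a, used_items) {
  stopifnot(inherits(a, "archetype"))
  used <- item_pairs(used_items)
  if (nrow(used) == 0L) {
    abx_stop("used_items must be non-empty", "abx_schema_error")
  }
  excl <- used$label %in% EXCLUDED_LABELS
  if (any(excl)) {
    abx_stop(sprintf("item(s) under excluded label(s): %s",
                     paste(item_keys(used)[excl], collapse = ", ")),
             "abx_schema_error")
  }
  undeclared <- !item_keys(used) %in% item_keys(a$items)
  if (any(undeclared)) {
    abx_stop(sprintf("item(s) not declared in %s: %s", a$id,
                     paste(item_keys(used)[undeclared], collapse = ", ")),
             "abx_schema_error")
  }
  cols <- data.frame(family = used$label, qualifier = used$name,
                     stringsAsFactors = FALSE)
  cols <- unique(cols)
  ord <- order(cols$family, cols$qualifier, method = "radix")
  cols <- cols[ord, , drop = FALSE]
  rownames(cols) <- NULL
  structure(list(archetype_id = a$id, columns = cols),
            class = "schema_fragment")
}

#' Union schema fragments into one table schema
#'
#' Step 1 of the mapping: the families of the table are the union of the
#' labels contributed by every mapped archetype. Family order is
#' deterministic — order of first appearance over the fragment list, with
#' each fragment's own families taken in bytewise order — so any permutation
#' of the input yields the same family *set*.
#'
#' @param fragments List of [map_archetype()] fragments.
#' @param name Table name.
#' @param role Table role (see [table_schema()]).
#' @return A [table_schema()].
#' @export
union_schema <- function(fragments, name, role = "dynamic") {
  fams <- character()
  for (f in fragments) {
    stopifnot(inherits(f, "schema_fragment"))
    fams <- c(fams, unique(f$columns$family))
  }
  table_schema(name, unique(fams), role)
}

#' Partition a catalog into static, dynamic and metadata tables
#'
#' Two data tables hold the virtual patient model: a *static* table for the
#' personal-details parameters (identification, demographics, contacts —
#' rarely altered) and a *dynamic* table for everything else (monitoring
#' parameters aggregated daily or per assessment, events, interventions).
#' A third table holds the archetype metadata content excluded from the
#' data tables (`Description`/`Attribution`).
#'
#' @param cat A [vpm_catalog()].
#' @param table_names Named character vector giving the `static`, `dynamic`
#'   and `metadata` table names.
#' @return List of three [table_schema()] objects: `static`, `dynamic`,
#'   `metadata`.
#' @export
partition_catalog <- function(cat,
                              table_names = c(static = "vpm_static",
                                              dynamic = "vpm_dynamic",
                                              metadata = "vpm_archetype_meta")) {
  stopifnot(inherits(cat, "vpm_catalog"),
            all(c("static", "dynamic", "metadata") %in% names(table_names)))
  frag_for <- function(p) {
    lapply(p$bindings, function(b) {
      map_archetype(cat$registry[[b$archetype]], b$items)
    })
  }
  is_static <- vapply(cat$parameters, function(p) {
    p$category == "personal_details"
  }, logical(1))
  static_frags <- unlist(lapply(cat$parameters[is_static], frag_for),
                         recursive = FALSE)
  dynamic_frags <- unlist(lapply(cat$parameters[!is_static], frag_for),
                          recursive = FALSE)
  list(
    static = union_schema(static_frags, table_names[["static"]], "static"),
    dynamic = union_schema(dynamic_frags, table_names[["dynamic"]],
                           "dynamic"),
    metadata = table_schema(table_names[["metadata"]], EXCLUDED_LABELS,
                            "metadata")
  )
}

#' Emit table DDL
#'
#' Renders the schema as one HBase-shell-style statement:
#' `create '<name>', '<family1>', '<family2>', ...` with families in schema
#' order.
#'
#' @param t A [table_schema()] with at least one family.
#' @return A single string.
#' @export
#' @examples
#' emit_ddl(table_schema("vpm_dynamic", c("Data", "Events")))
emit_ddl <- function(t) {
  stopifnot(inherits(t, "table_schema"))
  if (length(t$families) == 0L) {
    abx_stop(sprintf("table '%s' has no families; nothing to create", t$name),
             "abx_schema_error")
  }
  paste0("create '", t$name, "', ",
         paste0("'", t$families, "'", collapse = ", "))
}

#' Parse table DDL
#'
#' Inverse of [emit_ddl()] for statements it produces.
#'
#' @param text One `create '<name>', '<family>', ...` statement.
#' @param role Table role to attach (the DDL itself does not carry it).
#' @return A [table_schema()].
#' @export
parse_ddl <- function(text, role = "dynamic") {
  m <- regmatches(text, regexec("^create\\s+(.*)$", trimws(text)))[[1]]
  if (length(m) == 0L) {
    abx_stop(sprintf("not a create statement: %s", text), "abx_schema_error")
  }
  parts <- regmatches(m[2], gregexpr("'[^']*'", m[2]))[[1]]
  if (length(parts) < 2L) {
    abx_stop(sprintf("create statement needs a name and >= 1 family: %s",
                     text), "abx_schema_error")
  }
  parts <- gsub("^'|'$", "", parts)
  table_schema(parts[1], parts[-1], role)
}

#' Write a schema descriptor
#'
#' Serializes the three-table partition of a catalog — families per table
#' plus the per-archetype columns — as a YAML descriptor, alongside the DDL
#' text. Used by the `schema` command of the packaged CLI script.
#'
#' @param cat A [vpm_catalog()].
#' @param path Output path for the descriptor; the DDL is written next to it
#'   with extension `.ddl`.
#' @param table_names Passed to [partition_catalog()].
#' @return Invisibly, the list of schemas.
#' @export
write_schema_descriptor <- function(cat, path,
                                    table_names = c(static = "vpm_static",
                                                    dynamic = "vpm_dynamic",
                                                    metadata = "vpm_archetype_meta")) {
  schemas <- partition_catalog(cat, table_names)
  cols <- lapply(cat$parameters, function(p) {
    lapply(p$bindings, function(b) {
      frag <- map_archetype(cat$registry[[b$archetype]], b$items)
      list(archetype = b$archetype,
           columns = paste(frag$columns$family, frag$columns$qualifier,
                           sep = ":"))
    })
  })
  names(cols) <- vapply(cat$parameters, function(p) p$name, character(1))
  doc <- list(
    tables = lapply(schemas, function(s) {
      list(name = s$name, role = s$role, families = as.list(s$families))
    }),
    columns = cols
  )
  writeLines(yaml::as.yaml(doc, indent = 2), path)
  ddl <- vapply(schemas, emit_ddl, character(1))
  writeLines(ddl, paste0(path, ".ddl"))
  invisible(schemas)
}
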