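# The virtual patient model catalog: clinically meaningful parameters bound
# to archetypes, plus the archetype registry the bindings resolve against.

VPM_CATEGORIES <- c("personal_details", "monitoring", "events",
                    "interventions")
VPM_CADENCES <- c("static", "daily", "assessment", "event")

#' Define one virtual-patient-model parameter
#'
#' A parameter is a coherent clinical concept (e.g. "Heart rate") assigned
#' to one of four categories — personal details, monitoring parameters,
#' events, interventions — and bound to one or more archetypes together with
#' the archetype items the use case actually stores.
#'
#' @param name Parameter name (unique within a catalog).
#' @param category One of `"personal_details"`, `"monitoring"`, `"events"`,
#'   `"interventions"`.
#' @param bindings List of bindings, each `list(archetype = <id>, items =
#'   <"Label.Name" strings or label/name data.frame>)`. Must be non-empty.
#' @param subcategory Free-text subcategory (e.g. "Physiological
#'   measurements"), `""` if none.
#' @param cadence Sampling cadence: `"static"` (collected once),
#'   `"daily"` (device-aggregated daily), `"assessment"` (clinical
#'   assessment sessions), or `"event"` (recorded on occurrence).
#' @return Object of class `vpm_parameter`.
#' @export
vpm_parameter <- function(name, category, bindings, subcategory = "",
                          cadence = NULL) {
  if (!category %in% VPM_CATEGORIES) {
    abx_stop(sprintf("category must be one of %s",
                     paste(VPM_CATEGORIES, collapse = ", ")),
             "abx_catalog_error")
  }
  if (length(bindings) == 0L) {
    abx_stop(sprintf("parameter '%s' must bind at least one archetype", name),
             "abx_catalog_error")
  }
  if (is.null(cadence)) {
    cadence <- switch(category, personal_details = "static",
                      events = "event", interventions = "event", "daily")
  }
  stopifnot(cadence %in% VPM_CADENCES)
  bindings <- lapply(bindings, function(b) {
    stopifnot(!is.null(b$archetype))
    list(archetype = b$archetype, items = item_pairs(b$items))
  })
  structure(list(name = name, category = category,
                 subcategory = subcategory, cadence = cadence,
                 bindings = bindings),
            class = "vpm_parameter")
}

#' Assemble a catalog from parameters and an archetype registry
#'
#' @param parameters List of [vpm_parameter()] objects; names unique.
#' @param registry List of [archetype()] objects; ids unique. May contain
#'   archetypes not bound to any parameter (e.g. nested clusters or
#'   additional serious-game archetypes).
#' @param table_listed Character vector of archetype ids that appear in the
#'   published parameter tables (defaults to all registry ids).
#' @param meta Free-form catalog metadata list.
#' @return Object of class `vpm_catalog` with elements `parameters`,
#'   `registry` (named by id), `table_listed`, `meta`.
#' @export
vpm_catalog <- function(parameters = list(), registry = list(),
                        table_listed = NULL, meta = list()) {
  ids <- vapply(registry, function(a) a$id, character(1))
  if (anyDuplicated(ids)) {
    abx_stop("registry archetype ids must be unique", "abx_catalog_error")
  }
  names(registry) <- ids
  pnames <- vapply(parameters, function(p) p$name, character(1))
  if (anyDuplicated(pnames)) {
    abx_stop("parameter names must be unique", "abx_catalog_error")
  }
  if (is.null(table_listed)) table_listed <- ids
  cat <- structure(
    list(parameters = parameters, registry = registry,
         table_listed = table_listed, meta = meta),
    class = "vpm_catalog"
  )
  validate_catalog(cat)
  cat
}

validate_catalog <- function(cat) {
  for (p in cat$parameters) {
    for (b in p$bindings) {
      a <- cat$registry[[b$archetype]]
      if (is.null(a)) {
        abx_stop(sprintf("parameter '%s' binds unknown archetype '%s'",
                         p$name, b$archetype), "abx_catalog_error")
      }
      missing <- setdiff(item_keys(b$items), item_keys(a$items))
      if (length(missing)) {
        abx_stop(sprintf(
          "parameter '%s': item(s) %s not declared in %s",
          p$name, paste(missing, collapse = ", "), a$id),
          "abx_catalog_error")
      }
    }
  }
  bad <- setdiff(cat$table_listed, names(cat$registry))
  if (length(bad)) {
    abx_stop(sprintf("table_listed id(s) not in registry: %s",
                     paste(bad, collapse = ", ")), "abx_catalog_error")
  }
  invisible(cat)
}

#' @export
print.vpm_catalog <- function(x, ...) {
  cts <- catalog_counts(x)
  cat(sprintf(
    "<vpm_catalog> %d parameters, %d archetypes (%d reused, %d modified, %d new)\n",
    cts$parameters, length(x$registry), cts$reused, cts$modified, cts$new))
  invisible(x)
}

#' Load the packaged frailty virtual patient model catalog
#'
#' Reads the fixture manifests and the catalog index shipped with the
#' package: the 22 frailty-related parameters of the ageing-population
#' virtual patient model, the archetypes they bind (reused, modified or
#' newly developed), the nine additional serious-game cluster archetypes
#' that are not listed in the parameter tables, and one reused exemplar
#' evaluation archetype (clinical synopsis) used in worked examples.
#'
#' @param dir Directory holding `catalog.yaml` and a `manifests/` folder;
#'   defaults to the fixtures installed with the package.
#' @return A [vpm_catalog()].
#' @export
#' @examples
#' cat <- load_default_catalog()
#' catalog_counts(cat)
load_default_catalog <- function(dir = system.file("extdata",
                                                   package = "archebase")) {
  index_path <- file.path(dir, "catalog.yaml")
  man_dir <- file.path(dir, "manifests")
  if (!file.exists(index_path) || !dir.exists(man_dir)) {
    abx_stop(sprintf("catalog fixtures not found under %s", dir),
             "abx_catalog_error")
  }
  idx <- yaml::read_yaml(index_path)
  files <- sort(list.files(man_dir, pattern = "\\.yaml$", full.names = TRUE))
  registry <- lapply(files, read_manifest)
  parameters <- lapply(idx$parameters, function(p) {
    vpm_parameter(
      name = p$name, category = p$category,
      subcategory = if (is.null(p$subcategory)) "" else p$subcategory,
      cadence = p$cadence,
      bindings = lapply(p$bindings, function(b) {
        list(archetype = b$archetype, items = unlist(b$items))
      })
    )
  })
  vpm_catalog(parameters, registry,
              table_listed = unlist(idx$table_listed),
              meta = if (is.null(idx$meta)) list() else idx$meta)
}

#' Catalog cardinalities
#'
#' Counts the parameter rows and the distinct archetypes of each provenance
#' in a catalog. An archetype referenced by several parameters (the Fried
#' frailty-criteria archetype serves three) is counted once.
#' `new_shown_in_tables` counts only newly developed archetypes that appear
#' in the published parameter tables, excluding e.g. the additional
#' serious-game archetypes whose existence is stated but which are not
#' listed row by row.
#'
#' @param cat A [vpm_catalog()].
#' @return Named list: `parameters`, `reused`, `modified`, `new`,
#'   `new_shown_in_tables`.
#' @export
catalog_counts <- function(cat) {
  stopifnot(inherits(cat, "vpm_catalog"))
  prov <- vapply(cat$registry, function(a) a$provenance, character(1))
  ids <- names(cat$registry)
  list(
    parameters = length(cat$parameters),
    reused = sum(prov == "reused"),
    modified = sum(prov == "modified"),
    new = sum(prov == "new"),
    new_shown_in_tables = sum(prov == "new" & ids %in% cat$table_listed)
  )
}

#' Look up the parameter bound to an archetype
#'
#' @param cat A [vpm_catalog()].
#' @param archetype_id Archetype identifier.
#' @return The first [vpm_parameter()] whose bindings reference the
#'   archetype, or `NULL` if none does.
#' @export
parameter_for_archetype <- function(cat, archetype_id) {
  for (p in cat$parameters) {
    for (b in p$bindings) {
      if (b$archetype == archetype_id) return(p)
    }
  }
  NULL
}
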