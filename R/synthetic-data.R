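# Seeded generator of plausible virtual-patient-model records so ingestion,
# schema mapping and retrieval can be exercised with no external data.
# Value models are uniform draws inside the physiologic ranges declared per
# item in the fixture manifests; the generator's job is structural validity,
# not clinical realism (no temporal autocorrelation, no missingness).

#' Specify a synthetic cohort
#'
#' @param n_subjects Number of subjects (>= 1); subjects are numbered from
#'   1001 upwards, mirroring the worked examples.
#' @param start,end First and last monitoring day (inclusive).
#' @param daily_parameters Names of catalog parameters recorded once per
#'   subject per day (the device-measured monitoring set); `NULL` means all
#'   catalog parameters with cadence `"daily"`.
#' @param assessment_parameters Names of parameters recorded at clinical
#'   assessment sessions; `NULL` means all parameters with cadence
#'   `"assessment"`.
#' @param assessment_interval_days Days between assessment sessions
#'   (default 182, i.e. the six-monthly comprehensive geriatric assessment).
#' @param seed Integer seed; identical seeds give byte-identical streams.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, start, end, daily_parameters = NULL,
                        assessment_parameters = NULL,
                        assessment_interval_days = 182L, seed = 1L) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || start > end) {
    abx_stop("need valid dates with start <= end", "abx_cohort_error")
  }
  if (n_subjects < 1L) {
    abx_stop("n_subjects must be >= 1", "abx_cohort_error")
  }
  stopifnot(assessment_interval_days >= 1L)
  structure(
    list(n_subjects = as.integer(n_subjects), start = start, end = end,
         daily_parameters = daily_parameters,
         assessment_parameters = assessment_parameters,
         assessment_interval_days = as.integer(assessment_interval_days),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

resolve_parameters <- function(spec, cat) {
  by_cadence <- function(cad) {
    nm <- vapply(cat$parameters, function(p) p$name, character(1))
    nm[vapply(cat$parameters, function(p) p$cadence == cad, logical(1))]
  }
  pick <- function(given, cad) {
    if (is.null(given)) return(by_cadence(cad))
    nm <- vapply(cat$parameters, function(p) p$name, character(1))
    bad <- setdiff(given, nm)
    if (length(bad)) {
      abx_stop(sprintf("unknown parameter(s): %s",
                       paste(bad, collapse = ", ")), "abx_cohort_error")
    }
    given
  }
  list(daily = pick(spec$daily_parameters, "daily"),
       assessment = pick(spec$assessment_parameters, "assessment"),
       static = by_cadence("static"))
}

# One archetype carries each generated record: for the static
# personal-details record the demographic binding, otherwise the
# parameter's first binding.
generating_binding <- function(p, cat) {
  if (p$category == "personal_details") {
    for (b in p$bindings) {
      if (cat$registry[[b$archetype]]$klass == "DEMOGRAPHIC") return(b)
    }
  }
  p$bindings[[1L]]
}

GEN_WORDS <- c("stable", "improved", "declined", "normal", "reviewed",
               "unremarkable", "follow-up")

draw_value <- function(item) {
  kind <- item$value_kind
  lo <- item$range_min; hi <- item$range_max
  switch(kind,
    quantity = ,
    duration = {
      if (is.na(lo)) lo <- 0; if (is.na(hi)) hi <- 100
      sprintf("%.1f", stats::runif(1, lo, hi))
    },
    score = {
      if (is.na(lo)) lo <- 0; if (is.na(hi)) hi <- 10
      as.character(sample(seq.int(lo, hi), 1L))
    },
    boolean = sample(c("true", "false"), 1L),
    coded = {
      codes <- item$codes[[1]]
      if (length(codes) == 0L) codes <- paste0("code-", 1:4)
      sample(codes, 1L)
    },
    date = format(as.Date("1935-01-01") + sample.int(7300L, 1L), "%Y%m%d"),
    # text
    sample(GEN_WORDS, 1L)
  )
}

draw_record <- function(subject_id, date, binding, cat) {
  a <- cat$registry[[binding$archetype]]
  keys <- item_keys(a$items)
  values <- list()
  for (i in seq_len(nrow(binding$items))) {
    k <- paste(binding$items$label[i], binding$items$name[i], sep = ".")
    it <- a$items[match(k, keys), ]
    values[[it$label]][[it$name]] <- draw_value(it)
  }
  vpm_record(subject_id, date, binding$archetype, values)
}

#' Number of records a cohort specification implies
#'
#' Closed form: per subject, one static personal-details record, one record
#' per daily parameter per monitoring day, and one record per assessment
#' parameter per assessment session (sessions every
#' `assessment_interval_days`, the first on the start date).
#'
#' @param spec A [cohort_spec()].
#' @param cat A [vpm_catalog()].
#' @return Integer record count.
#' @export
expected_record_count <- function(spec, cat) {
  res <- resolve_parameters(spec, cat)
  days <- as.integer(spec$end - spec$start) + 1L
  visits <- ceiling(days / spec$assessment_interval_days)
  spec$n_subjects *
    (length(res$static) + days * length(res$daily) +
       visits * length(res$assessment))
}

#' Generate a synthetic record stream
#'
#' Produces, per subject: one static personal-details record, one record
#' per daily parameter per day, and assessment-parameter records at every
#' assessment session. All records validate against their archetypes by
#' construction, and quantity values fall inside the per-item ranges the
#' manifests declare. A single global seed drives per-subject substreams,
#' so each subject's records are reproducible independently of cohort size.
#'
#' @param spec A [cohort_spec()].
#' @param cat A [vpm_catalog()].
#' @return List of [vpm_record()]s, subjects in order, within subject:
#'   static, then daily records by date, then assessment records by session.
#' @export
#' @examples
#' cat <- load_default_catalog()
#' spec <- cohort_spec(2, "2018-03-01", "2018-03-03",
#'                     daily_parameters = "Blood pressure",
#'                     assessment_parameters = character(0), seed = 7)
#' length(generate_records(spec, cat))  # 2 static + 2 * 3 blood pressure
generate_records <- function(spec, cat) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(cat, "vpm_catalog"))
  res <- resolve_parameters(spec, cat)
  params <- cat$parameters
  names(params) <- vapply(params, function(p) p$name, character(1))
  days <- seq(spec$start, spec$end, by = "day")
  visit_idx <- seq(1L, length(days), by = spec$assessment_interval_days)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  })
  out <- vector("list", expected_record_count(spec, cat))
  k <- 0L
  for (i in seq_len(spec$n_subjects)) {
    # counter-based substream: subject i's stream depends only on (seed, i)
    set.seed((spec$seed * 1009L + i * 9973L) %% 2147483647L)
    subject <- as.character(1000L + i)
    for (pn in res$static) {
      k <- k + 1L
      out[[k]] <- draw_record(subject, NULL,
                              generating_binding(params[[pn]], cat), cat)
    }
    for (d in as.list(days)) {
      for (pn in res$daily) {
        k <- k + 1L
        out[[k]] <- draw_record(subject, d,
                                generating_binding(params[[pn]], cat), cat)
      }
    }
    for (d in as.list(days[visit_idx])) {
      for (pn in res$assessment) {
        k <- k + 1L
        out[[k]] <- draw_record(subject, d,
                                generating_binding(params[[pn]], cat), cat)
      }
    }
  }
  out[seq_len(k)]
}
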