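# Shared helpers: small builders and independent brute-force oracles.

keys_of <- function(df) paste(df$label, df$name, sep = ".")

# a minimal observation archetype built in code, independent of fixtures
tiny_observation <- function(id = "EHR-OBSERVATION.demo.v1",
                             provenance = "reused") {
  archetype(
    id,
    rbind(archetype_items("Data", c("Value", "Comment"), "quantity", "kg",
                          0, 100),
          archetype_items("Events", "Any event")),
    provenance = provenance
  )
}

# remove the added items from a modified archetype, recovering the
# published original (used to exercise the classify -> modify path)
strip_added <- function(a) {
  keep <- !(keys_of(a$items) %in% keys_of(a$added_items))
  archetype(a$id, a$items[keep, , drop = FALSE], metadata = a$metadata,
            provenance = "reused", aliases = a$aliases)
}

# --- unindexed replay oracle for the column store ---------------------------
# keeps every put in arrival order; queries replay the log naively,
# honouring the per-cell version retention limit.

oracle_new <- function(max_versions = 3L) {
  list(log = data.frame(rowkey = character(), family = character(),
                        qualifier = character(), version = numeric(),
                        value = character(), stringsAsFactors = FALSE),
       max_versions = max_versions)
}

oracle_put <- function(o, rowkey, family, qualifier, value, version) {
  o$log <- rbind(o$log, data.frame(rowkey = rowkey, family = family,
                                   qualifier = qualifier, version = version,
                                   value = value, stringsAsFactors = FALSE))
  o
}

oracle_retained <- function(o) {
  lg <- o$log
  if (nrow(lg) == 0L) return(lg)
  cell <- paste(lg$rowkey, lg$family, lg$qualifier, sep = "\x1f")
  keep <- unlist(lapply(split(seq_len(nrow(lg)), cell), function(idx) {
    idx[order(lg$version[idx], decreasing = TRUE)][
      seq_len(min(length(idx), o$max_versions))]
  }), use.names = FALSE)
  lg[sort(keep), , drop = FALSE]
}

oracle_get <- function(o, rowkey, family, qualifier, version = NULL) {
  lg <- oracle_retained(o)
  lg <- lg[lg$rowkey == rowkey & lg$family == family &
             lg$qualifier == qualifier, , drop = FALSE]
  if (!is.null(version)) lg <- lg[lg$version <= version, , drop = FALSE]
  if (nrow(lg) == 0L) return(NULL)
  lg$value[which.max(lg$version)]
}

oracle_scan <- function(o, start = NULL, stop = NULL) {
  lg <- oracle_retained(o)
  if (nrow(lg) == 0L) return(lg)
  cell <- paste(lg$rowkey, lg$family, lg$qualifier, sep = "\x1f")
  latest <- do.call(rbind, lapply(split(lg, cell), function(g) {
    g[which.max(g$version), , drop = FALSE]
  }))
  keys <- latest$rowkey
  ok <- rep(TRUE, nrow(latest))
  bytewise_lt <- function(a, b) {
    a != b && sort(c(a, b), method = "radix")[1L] == a
  }
  if (!is.null(start)) {
    ok <- ok & vapply(keys, function(k) !bytewise_lt(k, start), logical(1))
  }
  if (!is.null(stop)) {
    ok <- ok & vapply(keys, function(k) bytewise_lt(k, stop), logical(1))
  }
  latest <- latest[ok, , drop = FALSE]
  latest <- latest[order(latest$rowkey, latest$family, latest$qualifier,
                         method = "radix"), , drop = FALSE]
  rownames(latest) <- NULL
  latest
}

# canonical ordering of a record's nested value map, for equality checks
canon_values <- function(v) {
  v <- v[order(names(v))]
  lapply(v, function(x) x[order(names(x))])
}

# random ASCII rowkey tokens for property tests
random_subjects <- function(n) {
  vapply(seq_len(n), function(i) {
    paste(sample(c(LETTERS, letters, 0:9, "-"), sample(3:8, 1),
                 replace = TRUE), collapse = "")
  }, character(1))
}
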