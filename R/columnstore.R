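# Self-contained column-family store honouring the wide-column contract:
# families fixed by the schema, columns created on first write, rowkeys
# iterated in bytewise order, cells versioned with last-write-wins reads.
# cs_put/cs_get/cs_scan are S3 generics so a live-cluster adapter can
# provide its own methods against the same surface.

#' Create an in-memory column-family table
#'
#' The backend is an environment keyed by rowkey; each cell keeps up to
#' `max_versions` versioned values, newest first. Writers that do not supply
#' a version receive one from a per-table monotone counter.
#'
#' @param schema A [table_schema()].
#' @param max_versions Versions retained per cell (default 3, the common
#'   wide-column default); older versions are discarded.
#' @return Object of class `column_table` (an environment; mutated in
#'   place by writes).
#' @export
column_table <- function(schema, max_versions = 3L) {
  stopifnot(inherits(schema, "table_schema"), max_versions >= 1L)
  t <- new.env(parent = emptyenv())
  t$schema <- schema
  t$rows <- new.env(parent = emptyenv())
  t$counter <- 0L
  t$max_versions <- as.integer(max_versions)
  class(t) <- "column_table"
  t
}

#' @export
print.column_table <- function(x, ...) {
  cat(sprintf("<column_table> %s (%s): %d row(s), families %s\n",
              x$schema$name, x$schema$role, length(ls(x$rows)),
              paste(x$schema$families, collapse = ", ")))
  invisible(x)
}

cell_key <- function(family, qualifier) paste(family, qualifier, sep = "\x1f")

#' Write one cell
#'
#' @param t A [column_table()] (or adapter object).
#' @param rowkey Row key (byte-safe text).
#' @param family Column family; must belong to the table schema.
#' @param qualifier Column qualifier; columns are created on first write.
#' @param value Cell value, encoded as UTF-8 text (quantities as decimal
#'   strings).
#' @param version Integer version timestamp; defaults to the table's
#'   monotone write counter.
#' @return The version written, invisibly.
#' @export
cs_put <- function(t, rowkey, family, qualifier, value, version = NULL) {
  UseMethod("cs_put")
}

#' @export
cs_put.column_table <- function(t, rowkey, family, qualifier, value,
                                version = NULL) {
  if (!family %in% t$schema$families) {
    abx_stop(sprintf("unknown family '%s' for table '%s' (families: %s)",
                     family, t$schema$name,
                     paste(t$schema$families, collapse = ", ")),
             "abx_store_error")
  }
  stopifnot(is.character(rowkey), length(rowkey) == 1L, nzchar(rowkey))
  if (is.null(version)) {
    t$counter <- t$counter + 1L
    version <- t$counter
  } else {
    version <- as.integer(version)
    t$counter <- max(t$counter, version)
  }
  row <- t$rows[[rowkey]]
  if (is.null(row)) row <- list()
  key <- cell_key(family, qualifier)
  hist <- row[[key]]
  hist <- c(list(list(version = version, value = as.character(value))), hist)
  hist <- hist[order(vapply(hist, `[[`, numeric(1), "version"),
                     decreasing = TRUE)]
  if (length(hist) > t$max_versions) hist <- hist[seq_len(t$max_versions)]
  row[[key]] <- hist
  t$rows[[rowkey]] <- row
  invisible(version)
}

#' Read one cell
#'
#' @inheritParams cs_put
#' @param version Optional upper version bound; the newest value with
#'   version `<= version` is returned. Default: the latest value
#'   (last-write-wins).
#' @return The value string, or `NULL` if the cell was never written (or has
#'   no version within the bound).
#' @export
cs_get <- function(t, rowkey, family, qualifier, version = NULL) {
  UseMethod("cs_get")
}

#' @export
cs_get.column_table <- function(t, rowkey, family, qualifier,
                                version = NULL) {
  row <- t$rows[[rowkey]]
  if (is.null(row)) return(NULL)
  hist <- row[[cell_key(family, qualifier)]]
  if (is.null(hist)) return(NULL)
  if (!is.null(version)) {
    hist <- Filter(function(h) h$version <= version, hist)
    if (length(hist) == 0L) return(NULL)
  }
  hist[[1L]]$value
}

# Bytewise string comparison consistent with radix (C-locale) sort order,
# independent of the session collation.
bytewise_leq <- function(a, b) {
  if (a == b) return(TRUE)
  sort(c(a, b), method = "radix")[1L] == a
}

#' Scan a rowkey range
#'
#' Returns the latest version of every cell whose rowkey lies in the
#' half-open interval `[start, stop)`, in bytewise rowkey order. `NULL`
#' bounds are unbounded.
#'
#' @inheritParams cs_put
#' @param start,stop Rowkey range bounds (bytewise; `start <= stop`).
#' @return data.frame with columns `rowkey`, `family`, `qualifier`,
#'   `version`, `value`, ordered by (rowkey, family, qualifier).
#' @export
cs_scan <- function(t, start = NULL, stop = NULL) {
  UseMethod("cs_scan")
}

#' @export
cs_scan.column_table <- function(t, start = NULL, stop = NULL) {
  if (!is.null(start) && !is.null(stop) && !bytewise_leq(start, stop)) {
    abx_stop(sprintf("inverted scan range: start '%s' > stop '%s'",
                     start, stop), "abx_store_error")
  }
  keys <- sort(ls(t$rows, all.names = TRUE), method = "radix")
  if (!is.null(start)) {
    keys <- keys[vapply(keys, function(k) bytewise_leq(start, k),
                        logical(1))]
  }
  if (!is.null(stop)) {
    keys <- keys[vapply(keys, function(k) {
      bytewise_leq(k, stop) && k != stop
    }, logical(1))]
  }
  out <- lapply(keys, function(k) {
    row <- t$rows[[k]]
    ck <- names(row)
    fam <- sub("\x1f.*$", "", ck)
    qual <- sub("^[^\x1f]*\x1f", "", ck)
    ord <- order(fam, qual, method = "radix")
    data.frame(
      rowkey = k, family = fam[ord], qualifier = qual[ord],
      version = vapply(row[ord], function(h) h[[1L]]$version, numeric(1)),
      value = vapply(row[ord], function(h) h[[1L]]$value, character(1)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  if (length(out) == 0L) {
    return(data.frame(rowkey = character(), family = character(),
                      qualifier = character(), version = numeric(),
                      value = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# --- snapshot: line-delimited text persistence ------------------------------

escape_field <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

unescape_field <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[i], "", fixed = TRUE)[[1]]
    buf <- character(0); j <- 1L
    while (j <= length(chars)) {
      if (chars[j] == "\\" && j < length(chars)) {
        nxt <- chars[j + 1L]
        buf <- c(buf, switch(nxt, t = "\t", n = "\n", "\\" = "\\", nxt))
        j <- j + 2L
      } else {
        buf <- c(buf, chars[j]); j <- j + 1L
      }
    }
    out[i] <- paste(buf, collapse = "")
  }
  out
}

#' Write a table snapshot
#'
#' Persists every retained cell version as one tab-separated line
#' `rowkey, family, qualifier, version, value` (fields backslash-escaped),
#' rowkeys in bytewise order, versions oldest first so replaying the file
#' through [cs_put()] reproduces the table exactly.
#'
#' @param t A [column_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
snapshot_write <- function(t, path) {
  keys <- sort(ls(t$rows, all.names = TRUE), method = "radix")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (k in keys) {
    row <- t$rows[[k]]
    ck <- sort(names(row), method = "radix")
    for (key in ck) {
      fam <- sub("\x1f.*$", "", key)
      qual <- sub("^[^\x1f]*\x1f", "", key)
      for (h in rev(row[[key]])) {
        writeLines(paste(escape_field(c(k, fam, qual)[1]),
                         escape_field(fam), escape_field(qual),
                         format(h$version, scientific = FALSE),
                         escape_field(h$value), sep = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Read a table snapshot
#'
#' @param path Snapshot file written by [snapshot_write()].
#' @param schema The [table_schema()] of the table being restored.
#' @param max_versions Passed to [column_table()].
#' @return A new [column_table()] with the snapshot replayed into it.
#' @export
snapshot_read <- function(path, schema, max_versions = 3L) {
  t <- column_table(schema, max_versions)
  lines <- readLines(path, encoding = "UTF-8")
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 5L) {
      abx_stop(sprintf("malformed snapshot line: %s", ln), "abx_store_error")
    }
    f[c(1:3, 5)] <- unescape_field(f[c(1:3, 5)])
    cs_put(t, f[1], f[2], f[3], f[5], version = as.integer(f[4]))
  }
  t
}
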