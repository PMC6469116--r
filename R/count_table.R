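#' Construct a taxon-by-sample count table
#'
#' The central container: an integer read-count matrix with taxa as rows and
#' samples as columns. Rows whose ID starts with `spike_prefix` are the
#' spike-in (ERCC) rows; all remaining rows (host, microbial taxa) are
#' non-spike. Taxon IDs are opaque strings; no taxonomy is assumed.
#'
#' @param counts Integer matrix (taxa x samples) with unique row and column
#'   names; all cells non-negative integers, every column total > 0.
#' @param spike_prefix Taxon-ID prefix marking spike-in rows (default
#'   `"ERCC-"`).
#' @return An object of class `count_table` with elements `counts`,
#'   `is_spike` (named logical per taxon) and `spike_prefix`.
#' @seealso [load_counts()], [rpm()]
#' @export
count_table <- function(counts, spike_prefix = "ERCC-") {
  if (!is.matrix(counts)) stop("`counts` must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have taxon row names and sample column names", call. = FALSE)
  }
  dup_t <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_t)) {
    stop("duplicated taxon ID(s): ", paste(dup_t, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s)) {
    stop("duplicated sample ID(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(counts) || anyNA(counts) ||
      any(counts < 0) || any(counts != round(counts))) {
    bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
                 arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("counts must be non-negative integers; first offending cell at row '%s', column '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]), call. = FALSE)
  }
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total reads: ",
         paste(colnames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  }
  storage.mode(counts) <- "double"  # integer-valued; double avoids 32-bit overflow on totals
  structure(
    list(
      counts = counts,
      is_spike = stats::setNames(startsWith(rownames(counts), spike_prefix),
                                 rownames(counts)),
      spike_prefix = spike_prefix
    ),
    class = "count_table"
  )
}

#' Read a count table from disk
#'
#' Wide orientation: rows are taxa, columns are samples, the first column
#' holds the taxon ID and the header row the sample IDs. The delimiter is
#' inferred from the extension (`.csv` comma, otherwise tab). Use
#' `transpose = TRUE` for tables stored samples-by-taxa.
#'
#' @param path Path to a TSV/CSV file.
#' @param spike_prefix Taxon-ID prefix marking spike-in rows.
#' @param transpose Set `TRUE` when the file stores samples as rows.
#' @return A [count_table()].
#' @export
load_counts <- function(path, spike_prefix = "ERCC-", transpose = FALSE) {
  if (!file.exists(path)) stop("counts file not found: ", path, call. = FALSE)
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    stop("no data rows in ", path, call. = FALSE)
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop("no data rows in ", path, call. = FALSE)
  ids <- df[[1]]
  cells <- as.matrix(df[, -1, drop = FALSE])
  ok <- matrix(grepl("^\\s*[0-9]+\\s*$", cells), nrow = nrow(cells))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("non-integer count '%s' at row '%s', column '%s'",
                 trimws(cells[bad[1], bad[2]]), ids[bad[1]],
                 colnames(cells)[bad[2]]), call. = FALSE)
  }
  m <- matrix(as.numeric(cells), nrow = nrow(cells),
              dimnames = list(ids, colnames(cells)))
  if (transpose) m <- t(m)
  count_table(m, spike_prefix = spike_prefix)
}

#' Write a count table to disk
#'
#' Tab-delimited, first column `taxon_id`, UTF-8, LF line endings. A
#' write-then-[load_counts()] round trip preserves every count and ID.
#'
#' @param table A [count_table()].
#' @param path Output path (tab-delimited regardless of extension).
#' @return Invisibly, `path`.
#' @export
write_counts <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  m <- table$counts
  lines <- c(
    paste(c("taxon_id", colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], format(m[i, ], scientific = FALSE, trim = TRUE)),
            collapse = "\t")
    }, character(1))
  )
  write_lines_lf(lines, path)
  invisible(path)
}

#' Per-sample total read counts
#'
#' @param table A [count_table()].
#' @return Named numeric vector of per-sample totals over all rows.
#' @export
sample_totals <- function(table) {
  stopifnot(inherits(table, "count_table"))
  colSums(table$counts)
}

#' Per-sample spike-in (ERCC) read counts
#'
#' @param table A [count_table()].
#' @return Named numeric vector of per-sample totals over spike rows.
#' @export
spike_totals <- function(table) {
  stopifnot(inherits(table, "count_table"))
  colSums(table$counts[table$is_spike, , drop = FALSE])
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa (%d spike-in) x %d samples, %.3g total reads\n",
              nrow(x$counts), sum(x$is_spike), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

# internal: write UTF-8 lines with LF endings regardless of platform
write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
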