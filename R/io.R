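# Shared readers/writers.  Conventions used throughout the package:
# BED inputs are 0-based half-open; transcript positions are 1-based;
# all tables are plain TSV with a header line.

#' Read and validate a tab-separated table against a schema
#'
#' A thin, strict wrapper around [utils::read.delim()].  Every schema column
#' must be present; values are coerced to the declared type and validation
#' failures are reported with the offending line number (counting the header
#' as line 1).
#'
#' @param path Path to a TSV file with a header row.
#' @param schema Named character vector mapping column name to one of
#'   `"character"`, `"numeric"`, `"integer"`, or `"count"` (non-negative
#'   integer).
#' @param key Optional column name whose values must be unique.
#' @return A `data.frame` with the schema columns, in schema order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("protein_id\tscore", "Ssb\t1200.5"), f)
#' read_table(f, c(protein_id = "character", score = "numeric"))
read_table <- function(path, schema, key = NULL) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          check.names = FALSE, quote = "",
                          comment.char = "")
  if (nrow(df) == 0L) {
    warning("empty table: ", path, call. = FALSE)
  }
  missing <- setdiff(names(schema), names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- df[names(schema)]
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type == "character") next
    vals <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(vals) & !is.na(out[[col]]) & nzchar(out[[col]]))
    if (!length(bad)) bad <- which(is.na(vals))
    if (length(bad)) {
      stop(sprintf("%s: column '%s', line %d: non-numeric value '%s'",
                   path, col, bad[1L] + 1L, out[[col]][bad[1L]]),
           call. = FALSE)
    }
    if (type %in% c("integer", "count")) {
      if (any(vals != round(vals))) {
        bad <- which(vals != round(vals))[1L]
        stop(sprintf("%s: column '%s', line %d: non-integer value '%s'",
                     path, col, bad + 1L, out[[col]][bad]), call. = FALSE)
      }
      if (type == "count" && any(vals < 0)) {
        bad <- which(vals < 0)[1L]
        stop(sprintf("%s: column '%s', line %d: negative count '%s'",
                     path, col, bad + 1L, out[[col]][bad]), call. = FALSE)
      }
      vals <- as.integer(vals)
    }
    out[[col]] <- vals
  }
  if (!is.null(key)) {
    dup <- duplicated(out[[key]])
    if (any(dup)) {
      stop(sprintf("%s: column '%s', line %d: duplicate key '%s'",
                   path, key, which(dup)[1L] + 1L, out[[key]][which(dup)[1L]]),
           call. = FALSE)
    }
  }
  out
}

#' Write a data frame as TSV
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a BED3 file of genomic intervals
#'
#' Coordinates are 0-based, half-open, per the BED convention.
#'
#' @param path Path to a 3-column BED file (no header).
#' @return A `data.frame` with columns `chrom`, `start`, `end`.
#' @export
read_bed3 <- function(path) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "#",
                          col.names = c("chrom", "start", "end"),
                          colClasses = c("character", "numeric", "numeric"))
  if (any(df$end <= df$start)) {
    bad <- which(df$end <= df$start)[1L]
    stop(sprintf("%s: line %d: empty or inverted interval", path, bad),
         call. = FALSE)
  }
  df
}

#' Write intervals as BED3
#'
#' @param df Data frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed3 <- function(df, path) {
  utils::write.table(df[c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write/read a ground-truth sidecar as JSON
#'
#' Every synthetic-data generator returns a truth payload; these helpers
#' serialise it next to the generated files.
#'
#' @param truth A list (typically the `truth` element of a generator).
#' @param path JSON path.
#' @return `path` (write) or the parsed list (read).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
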