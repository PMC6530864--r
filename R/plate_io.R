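## Plate-level CSV I/O.
## Canonical plate columns (fixed order):
##   well_id,sample_id,assay_id,platform_id,signal_x,signal_y,is_ntc
## Signals are serialized with %.17g so write -> read is bit-lossless.

.plate_cols <- c("well_id", "sample_id", "assay_id", "platform_id",
                 "signal_x", "signal_y", "is_ntc")
.call_cols <- c("sample_id", "assay_id", "platform_id", "label", "quality")
.call_labels <- c("A11", "A12", "A22", "INVALID", "FAILED", "NTC")

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

.stop_format <- function(...) {
  stop(structure(class = c("snpplate_format_error", "error", "condition"),
                 list(message = sprintf(...), call = NULL)))
}

#' Read a plate fluorescence table
#'
#' Reads a per-well two-channel fluorescence CSV.  The \code{"plain"}
#' dialect expects exactly the canonical header
#' \code{well_id,sample_id,assay_id,platform_id,signal_x,signal_y,is_ntc}.
#' The \code{"instrument_export"} dialect additionally skips leading
#' metadata lines beginning with \code{#} or \code{*} (as emitted by
#' real-time PCR instrument software) and renames columns through
#' \code{column_map} before validation.
#'
#' @param path Path to a CSV file.
#' @param dialect \code{"plain"} (default) or \code{"instrument_export"}.
#' @param column_map Named character vector mapping file column names to
#'   canonical names, e.g. \code{c("Well Position" = "well_id")}.  Used by
#'   the instrument_export dialect.
#' @return A data frame of fluorescence points in file order, with the
#'   canonical columns; \code{signal_x}/\code{signal_y} numeric,
#'   \code{is_ntc} logical.
#' @export
read_plate <- function(path, dialect = c("plain", "instrument_export"),
                       column_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stop_format("plate file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "instrument_export") {
    skip <- grepl("^[#*]", lines)
    ## metadata preamble: leading run of flagged lines only
    n_skip <- if (any(!skip)) which(!skip)[1] - 1L else length(lines)
    lines <- lines[seq_len(length(lines)) > n_skip]
  }
  if (!length(lines)) .stop_format("empty plate file: %s", path)
  df <- utils::read.csv(text = lines, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (!is.null(column_map)) {
    hit <- names(df) %in% names(column_map)
    names(df)[hit] <- unname(column_map[names(df)[hit]])
  }
  missing <- setdiff(.plate_cols, names(df))
  if (length(missing))
    .stop_format("plate file %s is missing required column(s): %s",
                 path, paste(missing, collapse = ", "))
  df <- df[, .plate_cols]
  for (col in c("signal_x", "signal_y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      .stop_format("non-numeric %s in well %s (row %d)",
                   col, df$well_id[bad[1]], bad[1])
    df[[col]] <- v
  }
  df$is_ntc <- toupper(df$is_ntc) %in% c("TRUE", "T", "1", "YES")
  df
}

#' Write a plate fluorescence table
#'
#' Serializes fluorescence points to the canonical plate CSV with 17
#' significant digits, so that [read_plate()] recovers the numbers exactly.
#'
#' @param points Data frame with the canonical plate columns.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_plate <- function(points, path) {
  missing <- setdiff(.plate_cols, names(points))
  if (length(missing))
    .stop_format("points are missing column(s): %s",
                 paste(missing, collapse = ", "))
  out <- data.frame(well_id = as.character(points$well_id),
                    sample_id = as.character(points$sample_id),
                    assay_id = as.character(points$assay_id),
                    platform_id = as.character(points$platform_id),
                    signal_x = .fmt_num(points$signal_x),
                    signal_y = .fmt_num(points$signal_y),
                    is_ntc = ifelse(points$is_ntc, "TRUE", "FALSE"),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and write genotype call tables
#'
#' A call table has columns \code{sample_id, assay_id, platform_id, label,
#' quality}; \code{label} is one of A11, A12, A22, INVALID, FAILED, NTC and
#' \code{quality} is in \[0,1\] for genotype calls and missing (empty
#' field) otherwise.
#'
#' @param calls Data frame of calls.
#' @param path File path.
#' @return \code{write_calls} returns \code{path} invisibly;
#'   \code{read_calls} returns the call data frame with \code{quality}
#'   numeric (\code{NA} where missing).
#' @export
write_calls <- function(calls, path) {
  missing <- setdiff(.call_cols, names(calls))
  if (length(missing))
    .stop_format("call table is missing column(s): %s",
                 paste(missing, collapse = ", "))
  bad <- setdiff(unique(calls$label), .call_labels)
  if (length(bad))
    .stop_format("invalid call label(s): %s", paste(bad, collapse = ", "))
  out <- calls[, .call_cols]
  out$quality <- .fmt_num(as.numeric(calls$quality))
  out$quality[is.na(calls$quality)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  if (!file.exists(path)) .stop_format("call file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(.call_cols, names(df))
  if (length(missing))
    .stop_format("call file %s is missing required column(s): %s",
                 path, paste(missing, collapse = ", "))
  df <- df[, .call_cols]
  bad <- setdiff(unique(df$label), .call_labels)
  if (length(bad))
    .stop_format("invalid call label(s): %s", paste(bad, collapse = ", "))
  q <- df$quality
  q[q == ""] <- NA_character_
  df$quality <- as.numeric(q)
  df
}

#' Read and write ground-truth tables
#'
#' The truth table produced by [simulate_experiment()] records, per sample
#' and assay, the planted genotype and one \code{outcome_<platform>}
#' column per platform.
#'
#' @param truth Truth data frame.
#' @param path File path.
#' @return \code{write_truth} returns \code{path} invisibly;
#'   \code{read_truth} the data frame.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) .stop_format("truth file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
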