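# Long-format activity tables: one row per replicate measurement of a named
# response (enzyme activity or microbial count) in a treatment cell
# (dose x day x biostimulant) of the factorial design.

#' Build an activity table
#'
#' An activity table is the package's long-format container for replicate
#' measurements of one or more responses (soil enzyme activities or microbial
#' counts) across the factorial design. Each row is one replicate of one
#' response in one treatment cell.
#'
#' @param df data frame with columns `dose` (mg kg-1 DM, >= 0), `day`
#'   (sampling day, > 0), `biostimulant` (logical), `replicate` (positive
#'   integer), `value` (non-negative finite numeric) and optionally
#'   `response` (label; supplied via `response` if absent).
#' @param response response label used when `df` has no `response` column.
#' @param unit free-text unit string attached as the `"unit"` attribute.
#' @return a data frame of class `activity_table` with columns
#'   `response, dose, day, biostimulant, replicate, value`.
#' @examples
#' tab <- activity_table(
#'   data.frame(dose = c(0, 0, 50, 50), day = 15, biostimulant = FALSE,
#'              replicate = c(1, 2, 1, 2), value = c(10, 11, 4, 5)),
#'   response = "Ure", unit = "mg N-NH4 kg-1 h-1")
#' @export
activity_table <- function(df, response = NULL, unit = "") {
  df <- as.data.frame(df)
  if (!("response" %in% names(df))) {
    if (is.null(response)) {
      stop_soiltox("activity table needs a 'response' column or a response label",
                   "soiltox_schema_error")
    }
    df$response <- response
  }
  df <- df[, c("response", "dose", "day", "biostimulant", "replicate", "value")]
  df$biostimulant <- as.logical(df$biostimulant)
  structure(validate_activity_table(df), unit = unit,
            class = c("activity_table", "data.frame"))
}

#' Validate an activity table
#'
#' Checks the schema and value invariants: required columns present, doses
#' non-negative, days positive, values finite and non-negative.
#'
#' @param df a data frame (or `activity_table`).
#' @return the validated data frame, invisibly unchanged.
#' @export
validate_activity_table <- function(df) {
  needed <- c("response", "dose", "day", "biostimulant", "replicate", "value")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_soiltox(paste0("missing column(s): ", paste(missing, collapse = ", ")),
                 "soiltox_schema_error")
  }
  for (col in c("dose", "day", "replicate", "value")) {
    if (!is.numeric(df[[col]])) {
      stop_soiltox(paste0("column '", col, "' must be numeric"),
                   "soiltox_parse_error")
    }
  }
  if (anyNA(df$value) || any(!is.finite(df$value))) {
    bad <- which(!is.finite(df$value))[1]
    stop_soiltox(paste0("non-finite value in row ", bad), "soiltox_parse_error")
  }
  if (any(df$value < 0)) {
    bad <- which(df$value < 0)[1]
    stop_soiltox(paste0("negative value in row ", bad), "soiltox_validation_error")
  }
  if (any(df$dose < 0)) {
    stop_soiltox("doses must be >= 0", "soiltox_validation_error")
  }
  if (any(df$day <= 0)) {
    stop_soiltox("sampling days must be > 0", "soiltox_validation_error")
  }
  if (anyNA(df$biostimulant)) {
    stop_soiltox("biostimulant flag must be TRUE/FALSE", "soiltox_parse_error")
  }
  df
}

parse_logical_column <- function(x, col) {
  if (is.logical(x)) return(x)
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(key))
  out[key %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[key %in% c("false", "f", "0", "no", "n")] <- FALSE
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop_soiltox(paste0("cannot parse '", col, "' as logical in row ", bad),
                 "soiltox_parse_error")
  }
  out
}

read_delim_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) {
    stop_soiltox(paste0("file not found: ", path), "soiltox_io_error")
  }
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character",
                    comment.char = "", quote = "\"")
}

#' Read an activity table from a delimited file
#'
#' Expects a header with columns `dose, day, biostimulant, replicate, value`
#' (and optionally `response`), comma- or tab-separated (sniffed from the
#' first line unless `sep` is given), '.' decimal separator. Rows sharing the
#' same treatment cell are gathered as replicates in file order; no row is
#' ever silently dropped.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) sniffs `\t` vs `,`.
#' @inheritParams activity_table
#' @return an [activity_table].
#' @export
read_activity_table <- function(path, sep = NULL, response = NULL, unit = "") {
  raw <- read_delim_auto(path, sep)
  needed <- c("dose", "day", "biostimulant", "replicate", "value")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop_soiltox(paste0("missing column(s): ", paste(missing, collapse = ", ")),
                 "soiltox_schema_error")
  }
  for (col in c("dose", "day", "replicate", "value")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop_soiltox(paste0("cannot parse column '", col, "' as numeric in row ",
                          bad), "soiltox_parse_error")
    }
    raw[[col]] <- v
  }
  raw$biostimulant <- parse_logical_column(raw$biostimulant, "biostimulant")
  activity_table(raw, response = response, unit = unit)
}

#' Write an activity table to a delimited file
#'
#' Inverse of [read_activity_table()]: the round trip is the identity on all
#' valid tables.
#'
#' @param x an [activity_table].
#' @param path output path; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_activity_table <- function(x, path) {
  x <- validate_activity_table(x)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Per-cell replicate means of an activity table
#'
#' @param x an [activity_table].
#' @param agg aggregation function over replicates (default mean).
#' @return data frame `response, dose, day, biostimulant, mean, n`.
#' @export
activity_cell_means <- function(x, agg = mean) {
  x <- validate_activity_table(x)
  key <- interaction(x$response, x$dose, x$day, x$biostimulant, drop = TRUE)
  first <- !duplicated(key)
  out <- x[first, c("response", "dose", "day", "biostimulant")]
  out$mean <- as.numeric(tapply(x$value, key, agg))[as.integer(key[first])]
  out$n <- as.integer(table(key))[as.integer(key[first])]
  rownames(out) <- NULL
  out
}
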