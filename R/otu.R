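# OTU count tables with 5-rank lineages (phylum -> genus), the entry point of
# the metagenomic analytics. Raw sequencing is upstream and out of scope.

RANKS <- c("phylum", "class", "order", "family", "genus")
RANK_PREFIX <- c(phylum = "p__", class = "c__", order = "o__",
                 family = "f__", genus = "g__")

#' Build an OTU table
#'
#' Container for an OTU x sample count matrix with per-OTU taxonomic lineages
#' resolved phylum to genus. Unresolved ranks are empty strings and are pooled
#' into an "Unclassified" bucket by [aggregate_rank()], so no read is lost.
#'
#' @param counts non-negative integer matrix, OTUs in rows (rownames = OTU
#'   ids), samples in columns (colnames = sample labels).
#' @param lineage data frame with columns `phylum, class, order, family,
#'   genus`, one row per OTU in matrix row order; empty string marks an
#'   unresolved rank.
#' @param sample_map optional data frame `sample, dose, day, biostimulant`
#'   linking samples to treatment cells.
#' @return an object of class `otu_table`: a list with elements `counts`,
#'   `lineage`, `sample_map`.
#' @export
otu_table <- function(counts, lineage, sample_map = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_soiltox("counts must have OTU row names and sample column names",
                 "soiltox_schema_error")
  }
  lineage <- as.data.frame(lineage, stringsAsFactors = FALSE)
  obj <- structure(list(counts = counts, lineage = lineage,
                        sample_map = sample_map),
                   class = "otu_table")
  validate_otu_table(obj)
}

#' Validate an OTU table
#'
#' @param x an `otu_table`.
#' @return `x` if valid; otherwise a validation error stating the problem.
#' @export
validate_otu_table <- function(x) {
  counts <- x$counts
  if (anyDuplicated(rownames(counts))) {
    stop_soiltox("duplicate OTU ids", "soiltox_validation_error")
  }
  if (anyDuplicated(colnames(counts))) {
    stop_soiltox("duplicate sample labels", "soiltox_validation_error")
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop_soiltox("OTU counts must be non-negative", "soiltox_validation_error")
  }
  if (any(counts != round(counts))) {
    stop_soiltox("OTU counts must be integers", "soiltox_validation_error")
  }
  missing <- setdiff(RANKS, names(x$lineage))
  if (length(missing)) {
    stop_soiltox(paste0("lineage missing rank column(s): ",
                        paste(missing, collapse = ", ")),
                 "soiltox_schema_error")
  }
  if (nrow(x$lineage) != nrow(counts)) {
    stop_soiltox("lineage rows must match OTU rows", "soiltox_validation_error")
  }
  x
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples, %s total reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Split rank-prefixed lineage strings into rank slots
#'
#' `"p__Proteobacteria;c__Alphaproteobacteria"` becomes the 5-slot vector
#' `(Proteobacteria, Alphaproteobacteria, "", "", "")`; missing trailing ranks
#' pad with empty strings.
#'
#' @param lineage character vector of semicolon-separated, rank-prefixed
#'   lineage strings.
#' @return data frame with columns `phylum, class, order, family, genus`.
#' @export
parse_lineage <- function(lineage) {
  parts <- strsplit(as.character(lineage), ";", fixed = TRUE)
  out <- t(vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[a-z]__", "", p)
    length(p) <- length(RANKS)
    p[is.na(p)] <- ""
    p
  }, character(length(RANKS))))
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  names(out) <- RANKS
  out
}

format_lineage <- function(lineage) {
  apply(lineage[, RANKS, drop = FALSE], 1L, function(row) {
    keep <- max(c(0L, which(row != "")))
    if (keep == 0L) return(RANK_PREFIX[[1L]])
    paste0(RANK_PREFIX[seq_len(keep)], row[seq_len(keep)], collapse = ";")
  })
}

#' Read an OTU table from a delimited file
#'
#' Expects a tab- (default) or comma-delimited matrix whose first column is
#' `otu_id`, second `lineage` (semicolon-separated, rank-prefixed as in
#' `p__X;c__Y;...`), remaining columns one per sample. Counts are validated
#' as non-negative integers; duplicate ids are rejected.
#'
#' @param path file path.
#' @param sep separator; `NULL` sniffs tab vs comma.
#' @param sample_map optional sample-to-treatment map (data frame or CSV path
#'   with columns `sample, dose, day, biostimulant`).
#' @return an [otu_table].
#' @export
read_otu_table <- function(path, sep = NULL, sample_map = NULL) {
  raw <- read_delim_auto(path, sep)
  missing <- setdiff(c("otu_id", "lineage"), names(raw))
  if (length(missing)) {
    stop_soiltox(paste0("missing column(s): ", paste(missing, collapse = ", ")),
                 "soiltox_schema_error")
  }
  sample_cols <- setdiff(names(raw), c("otu_id", "lineage"))
  if (!length(sample_cols)) {
    stop_soiltox("no sample columns found", "soiltox_schema_error")
  }
  counts <- vapply(sample_cols, function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v)) {
      stop_soiltox(paste0("cannot parse counts in column '", col, "'"),
                   "soiltox_parse_error")
    }
    v
  }, numeric(nrow(raw)))
  counts <- matrix(counts, nrow = nrow(raw),
                   dimnames = list(raw$otu_id, sample_cols))
  if (is.character(sample_map) && length(sample_map) == 1L) {
    sample_map <- read_sample_map(sample_map)
  }
  otu_table(counts, parse_lineage(raw$lineage), sample_map = sample_map)
}

#' Write an OTU table to a tab-separated file
#'
#' Inverse of [read_otu_table()]; round-trips counts and lineages exactly.
#'
#' @param x an [otu_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path) {
  x <- validate_otu_table(x)
  df <- data.frame(otu_id = rownames(x$counts),
                   lineage = format_lineage(x$lineage),
                   x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample-to-treatment map
#'
#' @param path CSV with columns `sample, dose, day, biostimulant`.
#' @return data frame with those columns, `biostimulant` logical.
#' @export
read_sample_map <- function(path) {
  raw <- read_delim_auto(path)
  missing <- setdiff(c("sample", "dose", "day", "biostimulant"), names(raw))
  if (length(missing)) {
    stop_soiltox(paste0("missing column(s): ", paste(missing, collapse = ", ")),
                 "soiltox_schema_error")
  }
  raw$dose <- as.numeric(raw$dose)
  raw$day <- as.numeric(raw$day)
  raw$biostimulant <- parse_logical_column(raw$biostimulant, "biostimulant")
  raw
}
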