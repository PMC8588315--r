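# Biostimulation impact factor: IF = A_bs / A_baseline, the ratio of the
# replicate-mean response with the biostimulant to a baseline without its
# effect. IF > 1 encodes stimulation, IF < 1 inhibition, IF = 1 no effect.

#' Impact-factor matrix of a biostimulant
#'
#' For every response (enzyme or microbial group) and every dose x day cell,
#' computes IF = A_bs / A_baseline where A_bs is the replicate mean with the
#' biostimulant at that cell. Two baseline conventions are supported:
#'
#' * `"paired"` (default): the baseline is the *same* dose x day cell without
#'   the biostimulant, so IF isolates the amendment's effect at each
#'   contamination level (this is the reading under which IF < 1 means the
#'   amendment inhibits and IF > 1 stimulates).
#' * `"control-soil"`: the baseline is the uncontaminated (dose 0) cell of the
#'   same day *with* the biostimulant, so IF traces how contamination shifts
#'   the amended soil away from its own clean control.
#'
#' The two modes coincide at dose 0 under `"paired"` inputs restricted to the
#' amended arm only when the amendment is neutral; in general they answer
#' different questions, which is why both are kept selectable.
#'
#' @param with_bs [activity_table] holding the measurements of the amended
#'   (biostimulant) arm.
#' @param without_bs [activity_table] of the unamended arm (used by the
#'   `"paired"` mode; may be `NULL` for `"control-soil"`). Both tables are
#'   aggregated per response x dose x day cell; pre-split the arms before
#'   calling.
#' @param baseline_mode `"paired"` or `"control-soil"`.
#' @param agg replicate aggregation for the A values (default `mean`;
#'   `median` is the usual robust alternative).
#' @return an `if_matrix`: numeric matrix, responses in rows, treatment cells
#'   (`"<dose>|<day>"`) in columns, with attributes `baseline_mode` and
#'   `doses`/`days`. Cells with a zero or missing denominator are `NA`,
#'   never infinite.
#' @export
compute_if_matrix <- function(with_bs, without_bs = NULL,
                              baseline_mode = c("paired", "control-soil"),
                              agg = mean) {
  baseline_mode <- match.arg(baseline_mode)
  cell_means <- function(tab) {
    x <- validate_activity_table(tab)
    key <- interaction(x$response, x$dose, x$day, drop = TRUE)
    first <- !duplicated(key)
    out <- x[first, c("response", "dose", "day")]
    out$mean <- as.numeric(tapply(x$value, key, agg))[as.integer(key[first])]
    out
  }
  num <- cell_means(with_bs)
  if (baseline_mode == "paired") {
    if (is.null(without_bs)) {
      stop_soiltox("'paired' baseline needs the without-biostimulant table",
                   "soiltox_validation_error")
    }
    den <- cell_means(without_bs)
    den_key <- paste(den$response, den$dose, den$day)
    num_den_key <- paste(num$response, num$dose, num$day)
  } else {
    den <- num[num$dose == 0, , drop = FALSE]
    den_key <- paste(den$response, den$day)
    num_den_key <- paste(num$response, num$day)
  }
  denominators <- den$mean[match(num_den_key, den_key)]
  ratio <- ifelse(is.na(denominators) | denominators <= 0,
                  NA_real_, num$mean / denominators)

  responses <- unique(num$response)
  doses <- sort(unique(num$dose))
  days <- sort(unique(num$day))
  cells <- as.vector(t(outer(doses, days, paste, sep = "|")))
  mat <- matrix(NA_real_, nrow = length(responses), ncol = length(cells),
                dimnames = list(responses, cells))
  idx <- cbind(match(num$response, responses),
               match(paste(num$dose, num$day, sep = "|"), cells))
  mat[idx] <- ratio
  structure(mat, baseline_mode = baseline_mode, doses = doses, days = days,
            class = c("if_matrix", "matrix"))
}

#' Export an impact-factor matrix as CSV plus a JSON sidecar
#'
#' The CSV has responses as rows and `dose:day` composite columns; the JSON
#' sidecar records the baseline convention so exported matrices stay
#' self-describing.
#'
#' @param x an `if_matrix`.
#' @param path CSV output path; sidecar written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_if_matrix <- function(x, path) {
  df <- data.frame(response = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  names(df)[-1] <- sub("\\|", ":", colnames(x))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(baseline_mode = attr(x, "baseline_mode"),
                            doses = attr(x, "doses"), days = attr(x, "days")),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
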