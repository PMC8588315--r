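# Culture-based community indices computed from 10-day colony-emergence
# series: the colony development index CD (weighted toward early emergence,
# range 10-100) and the ecophysiological diversity index EP (Shannon-type
# entropy of the emergence-day distribution, range 0-1 in base 10).

N_OBS_DAYS <- 10L

check_emergence_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != N_OBS_DAYS) {
    stop_soiltox(sprintf("emergence series must have exactly %d daily counts",
                         N_OBS_DAYS), "soiltox_validation_error")
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop_soiltox("emergence counts must be non-negative", "soiltox_validation_error")
  }
  counts
}

#' Colony development index (CD)
#'
#' CD = 100 * sum(p_i / i) over observation days i = 1..10, where p_i is the
#' fraction of all colonies that first appeared on day i. Early emergence is
#' up-weighted (weight 1/i), so CD = 100 when every colony appears on day 1
#' and CD = 10 when every colony appears on day 10; fast-growing communities
#' (r-strategists) score high, slow or dormant ones (K-strategists) low.
#'
#' @param counts numeric vector of length 10: colonies *newly* appearing on
#'   each observation day (daily increments, not cumulative counts).
#' @return CD in \[10, 100\], or `NA_real_` when no colony emerged (the index
#'   is undefined, not zero).
#' @examples
#' compute_cd(c(100, rep(0, 9)))   # 100: all colonies on day 1
#' compute_cd(rep(10, 10))         # 10 * sum(1/(1:10)) ~ 29.29
#' @export
compute_cd <- function(counts) {
  counts <- check_emergence_counts(counts)
  total <- sum(counts)
  if (total == 0) return(NA_real_)
  100 * sum((counts / total) / seq_len(N_OBS_DAYS))
}

#' Ecophysiological diversity index (EP)
#'
#' EP = -sum(p_i * log(p_i)) over the emergence-day distribution, with the
#' usual 0*log(0) = 0 convention; p_i is the day-i fraction of the cumulative
#' colony total. In base 10 with 10 observation days EP lies in \[0, 1\]: 0
#' when all colonies appear on a single day, 1 when emergence is uniform.
#'
#' @inheritParams compute_cd
#' @param log_base logarithm base (default 10, which maps the 10-day window
#'   onto \[0, 1\]).
#' @return EP, or `NA_real_` when no colony emerged.
#' @examples
#' compute_ep(rep(5, 10))            # 1: uniform emergence
#' compute_ep(c(50, 50, rep(0, 8)))  # log10(2) ~ 0.301
#' @export
compute_ep <- function(counts, log_base = 10) {
  stopifnot(is.numeric(log_base), log_base > 0)
  counts <- check_emergence_counts(counts)
  total <- sum(counts)
  if (total == 0) return(NA_real_)
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = log_base))
}

#' Classify a community as r- or K-strategist from its CD index
#'
#' r-strategists multiply rapidly after plating (front-loaded emergence, high
#' CD); K-strategists grow slowly or sit dormant (low CD). No universal CD
#' cut-off exists; the default of 35 separates fast-growing organotroph-like
#' series from back-loaded actinobacteria-like series in the packaged
#' synthetic presets. The boundary is inclusive: `cd == threshold` is "r".
#'
#' @param cd CD value(s) from [compute_cd()].
#' @param threshold CD cut-off (default 35).
#' @return character vector, `"r-strategist"` or `"K-strategist"` (`NA` for
#'   undefined CD).
#' @export
classify_strategy <- function(cd, threshold = 35) {
  ifelse(is.na(cd), NA_character_,
         ifelse(cd >= threshold, "r-strategist", "K-strategist"))
}

#' Percent change of a treated group relative to control
#'
#' 100 * (mean(treated) - mean(control)) / mean(control): the signed summary
#' used throughout dose-response reporting (e.g. -76 means a 76% reduction).
#'
#' @param treated,control numeric replicate values.
#' @return signed percent, or `NA_real_` when the control mean is zero (the
#'   quantity is undefined).
#' @export
percent_change <- function(treated, control) {
  mc <- mean(control)
  if (!is.finite(mc) || mc == 0) return(NA_real_)
  100 * (mean(treated) - mc) / mc
}

#' CD/EP index table for a collection of colony-emergence series
#'
#' Computes CD, EP and the cumulative colony total for every series, either
#' per replicate or on counts pooled within each group x treatment cell.
#'
#' @param colonies data frame as produced by [generate_colony_counts()]:
#'   columns `group, dose, day, biostimulant, replicate, day1..day10`.
#' @param pooled if `TRUE`, replicate counts are summed within each cell
#'   before computing the indices; if `FALSE` (default) indices are computed
#'   per replicate.
#' @param log_base passed to [compute_ep()].
#' @return data frame `group, dose, day, biostimulant[, replicate], cd, ep,
#'   n_total`.
#' @export
colony_index_table <- function(colonies, pooled = FALSE, log_base = 10) {
  day_cols <- paste0("day", seq_len(N_OBS_DAYS))
  missing <- setdiff(c("group", "dose", "day", "biostimulant", day_cols),
                     names(colonies))
  if (length(missing)) {
    stop_soiltox(paste0("missing column(s): ", paste(missing, collapse = ", ")),
                 "soiltox_schema_error")
  }
  if (pooled) {
    key <- interaction(colonies$group, colonies$dose, colonies$day,
                       colonies$biostimulant, drop = TRUE)
    first <- !duplicated(key)
    out <- colonies[first, c("group", "dose", "day", "biostimulant")]
    mat <- apply(colonies[, day_cols], 2L,
                 function(v) tapply(v, key, sum)[as.integer(key[first])])
    mat <- matrix(mat, nrow = sum(first), dimnames = list(NULL, day_cols))
  } else {
    out <- colonies[, intersect(c("group", "dose", "day", "biostimulant",
                                  "replicate"), names(colonies))]
    mat <- as.matrix(colonies[, day_cols])
  }
  out$cd <- apply(mat, 1L, compute_cd)
  out$ep <- apply(mat, 1L, compute_ep, log_base = log_base)
  out$n_total <- rowSums(mat)
  rownames(out) <- NULL
  out
}
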