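# PCA of impact-factor matrices: treatment cells are the cases, responses
# (enzymes or microbial groups) the variables, so the ordination shows which
# dose x day combinations the biostimulant pushes in the same direction.

#' Principal component analysis of an impact-factor matrix
#'
#' Eigen-decomposes the correlation (default) or covariance matrix of the
#' cases-by-variables layout obtained by transposing the IF matrix (treatment
#' cells as cases, responses as variables). Components are ordered by
#' decreasing variance and each component's sign is fixed so that its
#' largest-magnitude loading is positive, making the output reproducible;
#' the absolute sign of a principal axis is arbitrary.
#'
#' Cases with any missing IF cell cannot enter the decomposition; they are
#' dropped and reported through the `dropped_cases` element rather than
#' silently imputed.
#'
#' @param x an `if_matrix` from [compute_if_matrix()], or any numeric matrix
#'   with variables in rows and cases in columns.
#' @param standardized if `TRUE` (default) variables are scaled to unit
#'   variance (correlation PCA); set `FALSE` for covariance PCA.
#' @return a `pca_report`: list with `explained_pct` (percent of total
#'   variance per component, summing to 100), `loadings` (variable x
#'   component, unit-norm columns), `scores` (case x component),
#'   `sdev`, `standardized`, `dropped_cases`.
#' @export
pca_if <- function(x, standardized = TRUE) {
  mat <- t(as.matrix(unclass(x)))  # cases x variables
  complete <- stats::complete.cases(mat)
  dropped <- rownames(mat)[!complete]
  mat <- mat[complete, , drop = FALSE]
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    stop_soiltox("PCA needs >= 2 complete cases and >= 2 variables",
                 "soiltox_validation_error")
  }
  sds <- apply(mat, 2L, stats::sd)
  if (standardized && any(sds == 0)) {
    stop_soiltox("constant variable: correlation PCA undefined",
                 "soiltox_degenerate_error")
  }
  if (all(sds == 0)) {
    stop_soiltox("rank-0 input: no variance to decompose",
                 "soiltox_degenerate_error")
  }
  fit <- stats::prcomp(mat, center = TRUE, scale. = standardized)
  # deterministic orientation: largest-magnitude loading positive per PC
  flip <- vapply(seq_len(ncol(fit$rotation)), function(j) {
    v <- fit$rotation[, j]
    sign(v[which.max(abs(v))]) < 0
  }, logical(1))
  fit$rotation[, flip] <- -fit$rotation[, flip, drop = FALSE]
  fit$x[, flip] <- -fit$x[, flip, drop = FALSE]
  var_comp <- fit$sdev^2
  structure(list(explained_pct = 100 * var_comp / sum(var_comp),
                 loadings = fit$rotation, scores = fit$x, sdev = fit$sdev,
                 center = fit$center,
                 scale = if (standardized) fit$scale else NULL,
                 standardized = standardized, dropped_cases = dropped),
            class = "pca_report")
}

#' @export
print.pca_report <- function(x, ...) {
  cat(sprintf("PCA (%s matrix): %d components\n",
              if (x$standardized) "correlation" else "covariance",
              length(x$explained_pct)))
  cat("explained variance (%):",
      paste(sprintf("%.1f", x$explained_pct), collapse = ", "), "\n")
  if (length(x$dropped_cases)) {
    cat("dropped incomplete cases:", paste(x$dropped_cases, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a PCA report as CSV loadings/scores plus a JSON summary
#'
#' @param x a `pca_report`.
#' @param prefix path prefix; writes `<prefix>_loadings.csv`,
#'   `<prefix>_scores.csv` and `<prefix>_summary.json`.
#' @return `prefix`, invisibly.
#' @export
write_pca_report <- function(x, prefix) {
  ld <- data.frame(variable = rownames(x$loadings), x$loadings,
                   check.names = FALSE)
  sc <- data.frame(case = rownames(x$scores), x$scores, check.names = FALSE)
  utils::write.table(ld, paste0(prefix, "_loadings.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(sc, paste0(prefix, "_scores.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(explained_pct = x$explained_pct,
                            standardized = x$standardized,
                            dropped_cases = x$dropped_cases),
                       paste0(prefix, "_summary.json"), digits = NA)
  invisible(prefix)
}
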