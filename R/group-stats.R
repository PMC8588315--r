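# Post-hoc inference on the factorial design: all-pairs Tukey HSD from the
# one-way ANOVA mean-square error, homogeneous groups rendered as a compact
# letter display, and Pearson dose correlations with a significance flag.

#' Tukey HSD homogeneous groups for one response
#'
#' Runs a one-way layout over a chosen design factor (by default the dose,
#' within whatever subset of the table is passed in), computes all pairwise
#' Tukey-adjusted p-values from the studentized range distribution using the
#' pooled ANOVA mean-square error, and labels the treatment levels with
#' homogeneous-group letters: two levels share a letter iff they are not
#' significantly different at `alpha`. Unequal replication uses the
#' Tukey-Kramer harmonic-mean form. With zero within-group variance the test
#' degenerates: identical means give p = 1, distinct means p = 0 (all pairs
#' significant).
#'
#' @param table an [activity_table].
#' @param response response label to test; required when the table carries
#'   several responses.
#' @param alpha family-wise significance level (default 0.01, the
#'   conventional stringent level for soil enzyme/microbial screening).
#' @param by character vector of design columns defining the one-way factor
#'   (default `"dose"`; e.g. `c("dose", "biostimulant")` for a dose-by-
#'   amendment layout).
#' @return a `homogeneous_grouping`: list with `labels` (ordered by
#'   descending mean), `means`, `n`, `letters`, `alpha`, `pairwise_p`
#'   (symmetric matrix of adjusted p-values).
#' @examples
#' tab <- activity_table(data.frame(
#'   dose = rep(c(0, 1, 50), each = 3), day = 15, biostimulant = FALSE,
#'   replicate = rep(1:3, 3), value = c(10, 11, 12, 10.5, 11.5, 12.5, 30, 31, 32)),
#'   response = "Deh")
#' tukey_hsd(tab, "Deh", alpha = 0.01)
#' @export
tukey_hsd <- function(table, response = NULL, alpha = 0.01, by = "dose") {
  table <- validate_activity_table(table)
  if (!is.null(response)) table <- table[table$response == response, ]
  if (length(unique(table$response)) > 1L) {
    stop_soiltox("table holds several responses; pick one via 'response'",
                 "soiltox_validation_error")
  }
  if (!nrow(table)) {
    stop_soiltox("no rows for the requested response", "soiltox_validation_error")
  }
  grp <- interaction(table[by], drop = TRUE, sep = "|")
  labels <- levels(grp)
  k <- length(labels)
  if (k < 2L) {
    stop_soiltox("need >= 2 treatment groups", "soiltox_validation_error")
  }
  n_i <- as.integer(table(grp))
  if (any(n_i < 2L)) {
    stop_soiltox("every group needs >= 2 replicates to estimate variance",
                 "soiltox_insufficient_replication")
  }
  means <- as.numeric(tapply(table$value, grp, mean))
  ss_within <- sum(tapply(table$value, grp,
                          function(v) sum((v - mean(v))^2)))
  df_err <- sum(n_i) - k
  mse <- ss_within / df_err

  p <- matrix(1, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      delta <- abs(means[i] - means[j])
      if (mse == 0) {
        # degenerate variance: identical data give p = 1, distinct means
        # are separated with certainty
        pij <- if (delta == 0) 1 else 0
      } else {
        # Tukey-Kramer: harmonic-mean standard error for unequal n
        se <- sqrt((mse / 2) * (1 / n_i[i] + 1 / n_i[j]))
        pij <- stats::ptukey(delta / se, nmeans = k, df = df_err,
                             lower.tail = FALSE)
      }
      p[i, j] <- p[j, i] <- pij
    }
  }

  ord <- order(means, decreasing = TRUE)
  sig <- p < alpha
  letters <- compact_letter_display(sig[ord, ord, drop = FALSE])
  letters <- letters[match(seq_len(k), ord)]
  structure(list(labels = labels, means = means, n = n_i, letters = letters,
                 alpha = alpha, pairwise_p = p, mse = mse, df = df_err),
            class = "homogeneous_grouping")
}

#' @export
print.homogeneous_grouping <- function(x, ...) {
  cat(sprintf("Tukey HSD homogeneous groups (alpha = %g)\n", x$alpha))
  print(data.frame(label = x$labels, mean = signif(x$means, 5), n = x$n,
                   letters = x$letters))
  invisible(x)
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-absorb algorithm: start from a single letter covering all labels;
#' for each significant pair, split every letter column still containing both
#' members; absorb columns that became subsets of others; assign letters
#' a, b, c, ... in first-use order. The result is a minimal-alphabet display
#' in which two labels share at least one letter iff they are *not*
#' significantly different. Labels are processed in input order, so passing
#' rows ordered by descending group mean yields the conventional "a on the
#' highest mean" display.
#'
#' @param significant square logical matrix; `[i, j]` is `TRUE` when labels i
#'   and j differ significantly. Must be symmetric with a `FALSE` diagonal.
#' @return character vector of letter strings, one per label, named by the
#'   matrix row names when present.
#' @examples
#' m <- matrix(FALSE, 3, 3); m[1, 3] <- m[3, 1] <- TRUE
#' compact_letter_display(m)  # "a", "ab", "b"
#' @export
compact_letter_display <- function(significant) {
  significant <- as.matrix(significant)
  n <- nrow(significant)
  if (n != ncol(significant) || !isTRUE(all(significant == t(significant)))) {
    stop_soiltox("significance matrix must be square and symmetric",
                 "soiltox_validation_error")
  }
  if (any(diag(significant))) {
    stop_soiltox("a label cannot differ from itself (diagonal must be FALSE)",
                 "soiltox_validation_error")
  }
  # columns of 'cols' are letters; start with one letter containing everyone
  cols <- list(rep(TRUE, n))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && significant[i, j]) {
        for (ci in seq_along(cols)) {
          col <- cols[[ci]]
          if (col[i] && col[j]) {
            # split: one copy loses i, the other loses j
            a <- col; a[i] <- FALSE
            b <- col; b[j] <- FALSE
            cols[[ci]] <- a
            cols[[length(cols) + 1L]] <- b
          }
        }
        # absorb columns that are subsets of another column
        keep <- rep(TRUE, length(cols))
        for (ci in seq_along(cols)) {
          for (cj in seq_along(cols)) {
            if (ci != cj && keep[ci] && keep[cj] &&
                all(cols[[ci]] | !cols[[cj]]) &&
                !identical(cols[[ci]], cols[[cj]])) {
              keep[cj] <- FALSE  # cj is a strict subset of ci
            }
          }
        }
        # drop exact duplicates too
        cols <- cols[keep]
        cols <- cols[!duplicated(cols)]
      }
    }
  }
  # letters in first-use order: a column's letter rank follows the position
  # of its first member (stable for ties, so creation order breaks them)
  first_member <- vapply(cols, function(col) which(col)[1], integer(1))
  cols <- cols[order(first_member)]
  letter_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- vapply(seq_len(n), function(i) {
    paste0(letter_pool[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, character(1))
  names(out) <- rownames(significant)
  out
}

#' Pearson correlation between dose and response with a significance flag
#'
#' Standard product-moment correlation with a two-sided t-test at `alpha`,
#' as used to flag dose-driven monotone trends in enzyme activities.
#'
#' @param doses numeric dose values.
#' @param response matched response values (typically replicate means).
#' @param alpha significance level for the flag (default 0.05).
#' @return list with `r`, `p_value`, `significant`, `n`. Constant input
#'   yields an undefined-correlation error.
#' @export
pearson_dose_correlation <- function(doses, response, alpha = 0.05) {
  if (length(doses) != length(response)) {
    stop_soiltox("doses and response must be the same length",
                 "soiltox_validation_error")
  }
  if (length(doses) < 3L) {
    stop_soiltox("need >= 3 matched pairs", "soiltox_validation_error")
  }
  if (stats::sd(doses) == 0 || stats::sd(response) == 0) {
    stop_soiltox("correlation undefined for a constant vector",
                 "soiltox_degenerate_error")
  }
  ct <- stats::cor.test(doses, response, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       significant = ct$p.value < alpha, n = length(doses))
}
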