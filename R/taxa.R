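# Metagenomic profile analytics on OTU tables: rank-wise aggregation with
# read conservation, relative-abundance filters, shared-taxon sets, and the
# two-proportion G-test (Yates) / Fisher exact hybrid with a continuity-
# corrected confidence interval for the difference between proportions.

#' Aggregate an OTU table at a taxonomic rank
#'
#' Sums counts over OTUs sharing the same label at the requested rank. OTUs
#' unresolved at that rank are pooled into an `"Unclassified"` bucket rather
#' than dropped, so per-sample totals are conserved exactly.
#'
#' @param x an [otu_table].
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return a `rank_profile`: list with `rank`, `counts` (taxon x sample),
#'   `proportions` (columns sum to 1), `sample_totals`.
#' @export
aggregate_rank <- function(x, rank) {
  x <- validate_otu_table(x)
  if (!rank %in% RANKS) {
    stop_soiltox(paste0("unknown rank '", rank, "'; expected one of: ",
                        paste(RANKS, collapse = ", ")),
                 "soiltox_validation_error")
  }
  label <- x$lineage[[rank]]
  label[is.na(label) | label == ""] <- "Unclassified"
  agg <- rowsum(x$counts, group = label)
  totals <- colSums(x$counts)
  if (any(totals == 0)) {
    stop_soiltox("every sample needs > 0 reads for proportions",
                 "soiltox_validation_error")
  }
  structure(list(rank = rank, counts = agg,
                 proportions = sweep(agg, 2L, totals, "/"),
                 sample_totals = totals),
            class = "rank_profile")
}

#' @export
print.rank_profile <- function(x, ...) {
  cat(sprintf("rank_profile (%s): %d taxa x %d samples\n", x$rank,
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Eliminate rare taxa from a rank profile
#'
#' Mirrors the usual profiling convention of dropping taxa whose relative
#' abundance is below the threshold: a taxon is *retained* when its
#' proportion reaches `threshold` in at least one sample (the boundary is
#' inclusive — exactly 1% survives a 1% filter, only strictly lower shares
#' are eliminated). Retained proportions stay expressed against the original
#' sample totals (no re-normalisation), and the removed mass per sample is
#' reported via the `removed_counts` element, so retained + removed always
#' reconstructs the input.
#'
#' @param profile a `rank_profile`.
#' @param threshold proportion cut-off in (0, 1); default 0.01.
#' @return a filtered `rank_profile` with extra elements `removed_counts`
#'   (per-sample mass of eliminated taxa) and `removed_taxa`.
#' @export
filter_min_proportion <- function(profile, threshold = 0.01) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop_soiltox("threshold must lie in (0, 1)", "soiltox_validation_error")
  }
  keep <- apply(profile$proportions, 1L, function(p) any(p >= threshold))
  removed <- profile$counts[!keep, , drop = FALSE]
  out <- profile
  out$counts <- profile$counts[keep, , drop = FALSE]
  out$proportions <- profile$proportions[keep, , drop = FALSE]
  out$removed_counts <- colSums(removed)
  out$removed_taxa <- rownames(removed)
  out$threshold <- threshold
  out
}

#' Taxa dominating the difference between two samples
#'
#' Lists the taxa whose relative abundances differ by at least `min_diff`
#' between two samples, ordered by descending absolute difference — the
#' "difference between proportions >= 1%" selection used when contrasting a
#' contaminated profile with its control.
#'
#' @param profile a `rank_profile`.
#' @param sample_a,sample_b sample labels.
#' @param min_diff minimum absolute proportion difference (default 0.01).
#' @return data frame `taxon, prop_a, prop_b, diff` (diff = a - b), ordered
#'   by `abs(diff)` descending.
#' @export
dominant_by_difference <- function(profile, sample_a, sample_b,
                                   min_diff = 0.01) {
  for (s in c(sample_a, sample_b)) {
    if (!s %in% colnames(profile$proportions)) {
      stop_soiltox(paste0("unknown sample '", s, "'"),
                   "soiltox_validation_error")
    }
  }
  pa <- profile$proportions[, sample_a]
  pb <- profile$proportions[, sample_b]
  d <- pa - pb
  sel <- abs(d) >= min_diff
  out <- data.frame(taxon = rownames(profile$proportions)[sel],
                    prop_a = pa[sel], prop_b = pb[sel], diff = d[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$diff)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Taxa shared across a set of samples
#'
#' The set of taxa reaching `min_proportion` in *every* listed sample — the
#' "core" taxa common to all treatment cells.
#'
#' @param profile a `rank_profile`.
#' @param samples sample labels (default all).
#' @param min_proportion per-sample retention threshold (default 0.01).
#' @return character vector of shared taxon labels.
#' @export
shared_taxa <- function(profile, samples = colnames(profile$proportions),
                        min_proportion = 0.01) {
  unknown <- setdiff(samples, colnames(profile$proportions))
  if (length(unknown)) {
    stop_soiltox(paste0("unknown sample(s): ", paste(unknown, collapse = ", ")),
                 "soiltox_validation_error")
  }
  if (length(samples) < 2L) {
    stop_soiltox("need >= 2 samples", "soiltox_validation_error")
  }
  p <- profile$proportions[, samples, drop = FALSE]
  rownames(p)[apply(p, 1L, function(v) all(v >= min_proportion))]
}

# Two-sided Fisher exact p for a 2x2 table, by hypergeometric enumeration:
# sum of the probabilities of all tables (same margins) no more probable
# than the observed one.
fisher_exact_p <- function(a, total_a, b, total_b) {
  m <- a + b                      # successes overall
  support <- max(0L, m - total_b):min(m, total_a)
  dens <- stats::dhyper(support, total_a, total_b, m)
  p_obs <- stats::dhyper(a, total_a, total_b, m)
  # relative tolerance guards against ties broken by floating-point noise
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

# G statistic with Yates continuity correction on a 2x2 table: each observed
# cell is shifted 0.5 toward its expectation (shift clamped at |O - E| so an
# exact fit stays exact), then G = 2 * sum(O * ln(O / E)).
g_test_yates <- function(obs) {
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  shift <- pmin(0.5, abs(obs - expd)) * sign(expd - obs)
  adj <- obs + shift
  terms <- ifelse(adj > 0, adj * log(adj / expd), 0)
  g <- 2 * sum(terms)
  list(statistic = max(g, 0), p_value = stats::pchisq(max(g, 0), df = 1,
                                                      lower.tail = FALSE))
}

#' Two-proportion test: G-test (Yates) with a Fisher exact fallback
#'
#' Compares a taxon's share in two pooled samples via the 2x2 contingency
#' table. The Yates-continuity-corrected G statistic is referred to
#' chi-squared(1); when any expected cell falls below `fisher_threshold`
#' (default 20, the convention of the STAMP profiling tool), the two-sided
#' Fisher exact p (full hypergeometric enumeration) is used instead and the
#' switch is recorded in `test_used`. The confidence interval for the
#' difference between proportions is the asymptotic normal (Wald) interval
#' with continuity correction.
#'
#' @param count_a,total_a taxon count and library size in sample A.
#' @param count_b,total_b taxon count and library size in sample B.
#' @param fisher_threshold expected-cell cut-off below which the Fisher exact
#'   branch is taken (default 20).
#' @param conf_level confidence level for the CI (default 0.95).
#' @return a `proportion_test` list: `diff` (prop A - prop B), `p_value`,
#'   `test_used` (`"g_yates"` or `"fisher"`), `ci_low`, `ci_high`,
#'   `statistic` (G, `NA` on the Fisher branch).
#' @export
two_proportion_test <- function(count_a, total_a, count_b, total_b,
                                fisher_threshold = 20, conf_level = 0.95) {
  if (total_a <= 0 || total_b <= 0) {
    stop_soiltox("totals must be > 0", "soiltox_validation_error")
  }
  if (count_a > total_a || count_b > total_b || count_a < 0 || count_b < 0) {
    stop_soiltox("counts must lie in [0, total]", "soiltox_validation_error")
  }
  obs <- matrix(c(count_a, total_a - count_a,
                  count_b, total_b - count_b), nrow = 2, byrow = TRUE)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (any(expd < fisher_threshold)) {
    test_used <- "fisher"
    statistic <- NA_real_
    p_value <- min(1, fisher_exact_p(count_a, total_a, count_b, total_b))
  } else {
    test_used <- "g_yates"
    g <- g_test_yates(obs)
    statistic <- g$statistic
    p_value <- g$p_value
  }
  p1 <- count_a / total_a
  p2 <- count_b / total_b
  diff <- p1 - p2
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- z * sqrt(p1 * (1 - p1) / total_a + p2 * (1 - p2) / total_b) +
    0.5 * (1 / total_a + 1 / total_b)   # continuity correction
  structure(list(diff = diff, p_value = p_value, test_used = test_used,
                 ci_low = diff - half, ci_high = diff + half,
                 statistic = statistic, conf_level = conf_level),
            class = "proportion_test")
}

#' Rank-profile proportion tests between two samples
#'
#' Applies [two_proportion_test()] to every taxon of a rank profile,
#' contrasting two samples (typically control vs top dose on one day), with
#' Benjamini-Hochberg adjusted p-values alongside the raw ones.
#'
#' @param profile a `rank_profile`.
#' @param sample_a,sample_b sample labels.
#' @inheritParams two_proportion_test
#' @return data frame `taxon, count_a, count_b, prop_a, prop_b, diff,
#'   p_value, p_adjust, test_used, ci_low, ci_high`.
#' @export
profile_proportion_tests <- function(profile, sample_a, sample_b,
                                     fisher_threshold = 20,
                                     conf_level = 0.95) {
  for (s in c(sample_a, sample_b)) {
    if (!s %in% colnames(profile$counts)) {
      stop_soiltox(paste0("unknown sample '", s, "'"),
                   "soiltox_validation_error")
    }
  }
  ta <- profile$sample_totals[[sample_a]]
  tb <- profile$sample_totals[[sample_b]]
  rows <- lapply(rownames(profile$counts), function(taxon) {
    ca <- profile$counts[taxon, sample_a]
    cb <- profile$counts[taxon, sample_b]
    tst <- two_proportion_test(ca, ta, cb, tb,
                               fisher_threshold = fisher_threshold,
                               conf_level = conf_level)
    data.frame(taxon = taxon, count_a = ca, count_b = cb,
               prop_a = ca / ta, prop_b = cb / tb, diff = tst$diff,
               p_value = tst$p_value, test_used = tst$test_used,
               ci_low = tst$ci_low, ci_high = tst$ci_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out[order(out$p_value), ]
}
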