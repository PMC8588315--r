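test_that("rank aggregation conserves reads and pools unresolved lineages", {
  lineage <- data.frame(
    phylum = c("X", "X", "X"), class = c("C1", "", "C2"),
    order = "", family = "", genus = "", stringsAsFactors = FALSE)
  counts <- matrix(c(5L, 3L, 2L, 1L, 4L, 7L), 3,
                   dimnames = list(paste0("OTU", 1:3), c("S1", "S2")))
  x <- otu_table(counts, lineage)

  ph <- aggregate_rank(x, "phylum")
  expect_equal(nrow(ph$counts), 1L)                       # single phylum row
  expect_equal(unname(ph$counts["X", ]), c(10, 12))       # column sums kept

  cl <- aggregate_rank(x, "class")
  expect_true("Unclassified" %in% rownames(cl$counts))
  expect_equal(unname(cl$counts["Unclassified", ]), c(3, 4))
  expect_error(aggregate_rank(x, "domain"), class = "soiltox_validation_error")

  set.seed(41)
  for (i in 1:25) {
    x <- rand_otu(n_taxa = sample(5:20, 1), n_samples = sample(2:5, 1))
    for (rank in c("phylum", "class", "order", "family", "genus")) {
      pr <- aggregate_rank(x, rank)
      expect_equal(colSums(pr$counts), colSums(x$counts))   # conservation
      expect_equal(unname(colSums(pr$proportions)),
                   rep(1, ncol(pr$counts)), tolerance = 1e-12)
    }
  }
})

test_that("the rare-taxon filter is inclusive at the boundary and accounts for removed mass", {
  counts <- matrix(c(990L, 10L, 995L, 5L), 2,
                   dimnames = list(c("OTUa", "OTUb"), c("S1", "S2")))
  lineage <- data.frame(phylum = c("A", "B"), class = "", order = "",
                        family = "", genus = "", stringsAsFactors = FALSE)
  pr <- aggregate_rank(otu_table(counts, lineage), "phylum")
  # taxon B sits at exactly 1.0% in S1 and 0.5% in S2: the boundary survives
  filt <- filter_min_proportion(pr, threshold = 0.01)
  expect_true(all(c("A", "B") %in% rownames(filt$counts)))  # 1.0% retained

  # a taxon strictly below threshold everywhere is eliminated
  counts2 <- matrix(c(995L, 5L, 996L, 4L), 2,
                    dimnames = list(c("OTUa", "OTUb"), c("S1", "S2")))
  lineage2 <- lineage
  pr2 <- aggregate_rank(otu_table(counts2, lineage2), "phylum")
  filt2 <- filter_min_proportion(pr2, threshold = 0.01)
  expect_false("B" %in% rownames(filt2$counts))
  expect_equal(unname(filt2$removed_counts), c(5, 4))
  # retained proportions are against original totals (no re-normalisation)
  expect_equal(unname(filt2$proportions["A", ]), c(0.995, 0.996))

  expect_error(filter_min_proportion(pr, threshold = 1.2),
               class = "soiltox_validation_error")

  set.seed(42)
  for (i in 1:25) {
    x <- rand_otu(n_taxa = sample(8:20, 1), n_samples = 3)
    pr <- aggregate_rank(x, "genus")
    filt <- filter_min_proportion(pr, threshold = 0.05)
    expect_equal(colSums(filt$counts) + filt$removed_counts,
                 colSums(pr$counts))                        # conservation
  }
})

test_that("difference-dominant taxa match a brute-force scan", {
  set.seed(43)
  x <- rand_otu(n_taxa = 15, n_samples = 3)
  pr <- aggregate_rank(x, "genus")
  expect_equal(nrow(dominant_by_difference(pr, "S1", "S1")), 0L) # identical
  expect_error(dominant_by_difference(pr, "S1", "nope"),
               class = "soiltox_validation_error")

  for (i in 1:20) {
    x <- rand_otu(n_taxa = sample(5:20, 1), n_samples = 2)
    pr <- aggregate_rank(x, "genus")
    thr <- runif(1, 0.005, 0.1)
    got <- dominant_by_difference(pr, "S1", "S2", min_diff = thr)
    want <- rownames(pr$proportions)[
      abs(pr$proportions[, "S1"] - pr$proportions[, "S2"]) >= thr]
    expect_setequal(got$taxon, want)
    expect_false(is.unsorted(rev(abs(got$diff))))           # sorted by |diff|
  }
})

test_that("shared taxa are the intersection of per-sample retained sets", {
  counts <- matrix(c(100L, 0L, 0L, 100L), 2,
                   dimnames = list(c("OTUa", "OTUb"), c("S1", "S2")))
  lineage <- data.frame(phylum = c("A", "B"), class = "", order = "",
                        family = "", genus = "", stringsAsFactors = FALSE)
  pr <- aggregate_rank(otu_table(counts, lineage), "phylum")
  expect_length(shared_taxa(pr), 0L)                        # disjoint supports

  set.seed(44)
  for (i in 1:15) {
    x <- rand_otu(n_taxa = sample(8:20, 1), n_samples = sample(2:4, 1))
    pr <- aggregate_rank(x, "genus")
    thr <- runif(1, 0.01, 0.1)
    got <- shared_taxa(pr, min_proportion = thr)
    per_sample <- lapply(colnames(pr$proportions), function(s) {
      rownames(pr$proportions)[pr$proportions[, s] >= thr]
    })
    expect_setequal(got, Reduce(intersect, per_sample))
  }
  # identical columns: everything retained anywhere is shared
  same <- cbind(S1 = c(60L, 40L), S2 = c(60L, 40L))
  rownames(same) <- c("OTUa", "OTUb")
  pr2 <- aggregate_rank(otu_table(same, lineage), "phylum")
  expect_setequal(shared_taxa(pr2), c("A", "B"))
})

test_that("the two-proportion hybrid test honours its contracts", {
  # identical proportions: no difference, p = 1, CI spans zero
  r <- two_proportion_test(50, 100, 50, 100)
  expect_equal(r$diff, 0)
  expect_equal(r$p_value, 1)
  expect_lt(r$ci_low, 0); expect_gt(r$ci_high, 0)
  expect_equal(r$test_used, "g_yates")

  # tiny expected cells switch to the Fisher branch
  rf <- two_proportion_test(0, 5, 5, 5)
  expect_equal(rf$test_used, "fisher")

  expect_error(two_proportion_test(6, 5, 1, 5),
               class = "soiltox_validation_error")

  # symmetry: swapping samples negates diff, mirrors the CI, keeps p
  set.seed(45)
  for (i in 1:50) {
    ta <- sample(5:500, 1); tb <- sample(5:500, 1)
    a <- sample(0:ta, 1); b <- sample(0:tb, 1)
    r1 <- two_proportion_test(a, ta, b, tb)
    r2 <- two_proportion_test(b, tb, a, ta)
    expect_equal(r1$diff, -r2$diff)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
    expect_equal(r1$ci_low, -r2$ci_high, tolerance = 1e-12)
    expect_true(r1$ci_low <= r1$diff && r1$diff <= r1$ci_high)
    expect_true(r1$p_value >= 0 && r1$p_value <= 1)
  }
})

test_that("the Fisher branch agrees with fisher.test and the branch rule is exact", {
  set.seed(46)
  for (i in 1:200) {
    ta <- sample(2:25, 1); tb <- sample(2:25, 1)
    a <- sample(0:ta, 1); b <- sample(0:tb, 1)
    r <- two_proportion_test(a, ta, b, tb, fisher_threshold = 1e9)
    oracle <- stats::fisher.test(matrix(c(a, ta - a, b, tb - b), 2,
                                        byrow = TRUE))$p.value
    expect_equal(r$p_value, min(1, oracle), tolerance = 1e-12)

    # branch switch triggers exactly when any expected cell < threshold
    thr <- runif(1, 0.5, 30)
    obs <- matrix(c(a, ta - a, b, tb - b), 2, byrow = TRUE)
    expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    r2 <- two_proportion_test(a, ta, b, tb, fisher_threshold = thr)
    expect_equal(r2$test_used,
                 if (any(expd < thr)) "fisher" else "g_yates")
  }
})

test_that("the Yates correction washes out as counts grow, even at near-ties", {
  g_uncorrected <- function(obs) {
    expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
    g <- 2 * sum(ifelse(obs > 0, obs * log(obs / expd), 0))
    stats::pchisq(g, df = 1, lower.tail = FALSE)
  }
  # near-tie tables are the worst case for the continuity correction: the
  # p discrepancy shrinks as 1/sqrt(n)
  gap_at <- function(n) {
    a <- round(0.25 * n); b <- round(0.2505 * n)
    r <- two_proportion_test(a, n, b, n)
    expect_equal(r$test_used, "g_yates")
    abs(r$p_value - g_uncorrected(matrix(c(a, n - a, b, n - b), 2,
                                         byrow = TRUE)))
  }
  gaps <- vapply(c(4e4, 4e5, 4e6), gap_at, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-3)
})

test_that("profile-wide proportion tests adjust p-values and keep conservation", {
  set.seed(48)
  x <- rand_otu(n_taxa = 10, n_samples = 2, lambda = 200)
  pr <- aggregate_rank(x, "genus")
  tests <- profile_proportion_tests(pr, "S1", "S2")
  expect_equal(nrow(tests), nrow(pr$counts))
  expect_true(all(tests$p_adjust >= tests$p_value - 1e-15))
  expect_true(all(tests$test_used %in% c("g_yates", "fisher")))
})
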