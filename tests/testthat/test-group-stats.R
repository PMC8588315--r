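make_oneway <- function(values_by_group) {
  k <- length(values_by_group)
  df <- data.frame(
    dose = rep(seq_len(k), lengths(values_by_group)),
    day = 15, biostimulant = FALSE,
    replicate = unlist(lapply(lengths(values_by_group), seq_len)),
    value = unlist(values_by_group))
  activity_table(df, response = "x")
}

test_that("Tukey HSD reproduces textbook cases and the degenerate contracts", {
  # identical replicate sets: nothing to separate, both groups lettered "a"
  hg <- tukey_hsd(make_oneway(list(c(1, 2, 3), c(1, 2, 3))), alpha = 0.01)
  expect_equal(unname(hg$letters), c("a", "a"))
  expect_equal(hg$pairwise_p[1, 2], 1)

  # close pair + distant third at alpha = 0.01
  hg <- tukey_hsd(make_oneway(list(c(1, 2, 3), c(1.1, 2.1, 3.1),
                                   c(10, 11, 12))), alpha = 0.01)
  sets <- strsplit(unname(hg$letters), "")
  expect_gt(length(intersect(sets[[1]], sets[[2]])), 0)
  expect_equal(length(intersect(sets[[1]], sets[[3]])), 0)
  expect_equal(length(intersect(sets[[2]], sets[[3]])), 0)

  # five well-separated groups: every group its own letter
  hg <- tukey_hsd(make_oneway(lapply(c(10, 100, 200, 300, 400),
                                     function(m) m + c(-0.1, 0, 0.1))),
                  alpha = 0.01)
  expect_equal(length(unique(hg$letters)), 5L)
  expect_true(all(nchar(hg$letters) == 1L))

  # degenerate variance with unequal means: all pairs separated
  hg <- tukey_hsd(make_oneway(list(c(1, 1), c(2, 2))), alpha = 0.01)
  expect_equal(hg$pairwise_p[1, 2], 0)
  expect_equal(length(unique(hg$letters)), 2L)

  expect_error(tukey_hsd(make_oneway(list(c(1, 2), 3))),
               class = "soiltox_insufficient_replication")
})

test_that("Tukey-adjusted p-values match TukeyHSD on random one-way layouts", {
  set.seed(31)
  for (rep in 1:25) {
    k <- sample(3:6, 1)
    n <- sample(3:5, 1)
    values <- lapply(seq_len(k), function(i) {
      abs(rnorm(n, mean = 10 + i, sd = 1.5))
    })
    tab <- make_oneway(values)
    hg <- tukey_hsd(tab, alpha = 0.01)

    fit <- stats::aov(value ~ factor(dose), data = as.data.frame(tab))
    oracle <- stats::TukeyHSD(fit)$`factor(dose)`
    for (row in rownames(oracle)) {
      ij <- strsplit(row, "-", fixed = TRUE)[[1]]
      expect_equal(hg$pairwise_p[ij[1], ij[2]], oracle[row, "p adj"],
                   tolerance = 1e-6)
    }
    # p-values live in [0,1] and are permutation-invariant to group order
    expect_true(all(hg$pairwise_p >= 0 & hg$pairwise_p <= 1))
    perm <- sample(k)
    tab2 <- tab
    tab2$dose <- perm[tab$dose]
    hg2 <- tukey_hsd(activity_table(tab2), alpha = 0.01)
    expect_equal(hg2$pairwise_p[as.character(perm[as.integer(rownames(hg$pairwise_p))]),
                                as.character(perm[as.integer(colnames(hg$pairwise_p))])],
                 hg$pairwise_p, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("compact letter display encodes exactly the significance relation", {
  # no significant pair: a single shared letter
  expect_equal(unname(compact_letter_display(matrix(FALSE, 4, 4))),
               rep("a", 4))
  # all pairs significant: one distinct letter each
  m <- !diag(5) > 0
  expect_equal(unname(compact_letter_display(m)), letters[1:5])
  # chain A~B, B~C, A!=C
  m <- matrix(FALSE, 3, 3); m[1, 3] <- m[3, 1] <- TRUE
  expect_equal(unname(compact_letter_display(m)), c("a", "ab", "b"))
  # invalid inputs
  bad <- matrix(FALSE, 2, 3)
  expect_error(compact_letter_display(bad), class = "soiltox_validation_error")
  asym <- matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)
  expect_error(compact_letter_display(asym), class = "soiltox_validation_error")

  set.seed(32)
  for (rep in 1:150) {
    n <- sample(2:8, 1)
    sig <- rand_sig_matrix(n, p = runif(1, 0.1, 0.8))
    lets <- compact_letter_display(sig)
    expect_true(cld_encodes_relation(lets, sig))
  }
})

test_that("Pearson dose correlation flags linear trends with the right sign", {
  doses <- c(0, 0.1, 1, 10, 50)
  r <- pearson_dose_correlation(doses, 2 * doses + 1)
  expect_equal(r$r, 1)
  expect_true(r$significant)
  expect_equal(pearson_dose_correlation(doses, -doses)$r, -1)

  # affine response transform: r(x, a*y + b) = sign(a) * r(x, y)
  set.seed(33)
  y <- rnorm(10); x <- rnorm(10)
  r0 <- pearson_dose_correlation(x, y)$r
  expect_equal(pearson_dose_correlation(x, -3 * y + 2)$r, -r0)
  expect_true(abs(r0) <= 1)

  # independent response at large n: small r, not significant
  xx <- seq_len(200)
  yy <- rnorm(200)
  ri <- pearson_dose_correlation(xx, sample(yy))
  expect_lt(abs(ri$r), 0.2)
  expect_false(ri$significant)

  expect_error(pearson_dose_correlation(doses, rep(1, 5)),
               class = "soiltox_degenerate_error")
  expect_error(pearson_dose_correlation(1:2, 1:2),
               class = "soiltox_validation_error")
})

test_that("PCA of IF matrices matches the SVD and honours its conventions", {
  # rank-1 input: the single direction carries all the variance
  v <- c(1, 2, 3, 4, 5, 6)
  m <- outer(c(1, 2, 3), v) + 5       # 3 variables x 6 cases
  rep1 <- pca_if(m, standardized = FALSE)
  expect_equal(rep1$explained_pct[1], 100)

  # duplicated variables load identically on every retained component
  set.seed(34)
  base <- matrix(rnorm(4 * 10), 4, 10)
  dup <- rbind(base, base[1, , drop = FALSE])
  repd <- pca_if(dup, standardized = FALSE)
  keep <- repd$sdev > 1e-8
  expect_equal(repd$loadings[1, keep], repd$loadings[5, keep],
               ignore_attr = TRUE, tolerance = 1e-8)

  for (i in 1:20) {
    m <- matrix(rnorm(7 * 15), 7, 15)       # variables x cases
    rp <- pca_if(m, standardized = TRUE)
    expect_equal(sum(rp$explained_pct), 100, tolerance = 1e-9)
    # independent oracle: singular values of the scaled, centered case matrix
    x <- scale(t(m), center = TRUE, scale = TRUE)
    sv <- svd(x)$d^2 / (nrow(x) - 1)
    expect_equal(rp$explained_pct, 100 * sv / sum(sv), tolerance = 1e-8)
    # loadings are unit norm; scores back-project to the scaled data
    expect_equal(colSums(rp$loadings^2), rep(1, ncol(rp$loadings)),
                 ignore_attr = TRUE, tolerance = 1e-8)
    expect_equal(rp$scores %*% t(rp$loadings), x, ignore_attr = TRUE,
                 tolerance = 1e-8)
    # orientation: the dominant loading of each component is positive
    apex <- apply(rp$loadings, 2, function(u) u[which.max(abs(u))])
    expect_true(all(apex > 0))
  }
})
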