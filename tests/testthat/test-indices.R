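test_that("CD matches its closed forms and stays inside [10, 100]", {
  # all colonies on day 1 / day 10 pin the extremes
  expect_equal(compute_cd(c(100, rep(0, 9))), 100)
  expect_equal(compute_cd(c(rep(0, 9), 100)), 10)
  # uniform emergence: CD = 10 * H_10 (harmonic sum)
  expect_equal(compute_cd(rep(10, 10)), 10 * sum(1 / (1:10)))
  # an empty series has no index, not a zero
  expect_identical(compute_cd(rep(0, 10)), NA_real_)
  expect_error(compute_cd(1:5), class = "soiltox_validation_error")

  set.seed(21)
  for (i in 1:200) {
    counts <- rpois(10, 5)
    if (sum(counts) == 0) counts[sample(10, 1)] <- 1L
    cd <- compute_cd(counts)
    expect_gte(cd, 10); expect_lte(cd, 100)
    # scale invariance: CD depends only on proportions
    expect_equal(compute_cd(counts * sample(2:7, 1)), cd)
  }
})

test_that("moving a colony to an earlier day never decreases CD", {
  set.seed(22)
  for (i in 1:100) {
    counts <- rpois(10, 3)
    nz <- which(counts > 0)
    if (!length(nz)) next
    from <- sample(rep(nz, 2), 1)
    if (from == 1) next
    to <- sample(seq_len(from - 1), 1)
    moved <- counts
    moved[from] <- moved[from] - 1
    moved[to] <- moved[to] + 1
    expect_gte(compute_cd(moved), compute_cd(counts))
  }
})

test_that("EP matches entropy closed forms, bounds and uniqueness of extremes", {
  expect_equal(compute_ep(c(0, 0, 40, rep(0, 7))), 0)     # one-day emergence
  expect_equal(compute_ep(rep(5, 10)), 1)                 # uniform, base 10
  expect_equal(compute_ep(c(50, 50, rep(0, 8))), log10(2))
  expect_identical(compute_ep(rep(0, 10)), NA_real_)
  # the log base is a parameter: natural log rescales by ln(10)
  expect_equal(compute_ep(rep(5, 10), log_base = exp(1)), log(10))

  set.seed(23)
  for (i in 1:200) {
    counts <- rpois(10, 5)
    if (sum(counts) == 0) counts[sample(10, 1)] <- 1L
    ep <- compute_ep(counts)
    expect_gte(ep, 0); expect_lte(ep, 1)
    expect_equal(compute_ep(counts * 3), ep)             # scale invariance
    uniform <- length(unique(counts)) == 1L
    single <- sum(counts > 0) == 1L
    if (!uniform) expect_lt(ep, 1)                       # max iff uniform
    expect_identical(ep == 0, single)                    # zero iff one day
  }
})

test_that("percent change is the signed mean ratio summary", {
  expect_equal(percent_change(c(5, 5), c(5, 5)), 0)
  expect_equal(percent_change(0.24 * c(10, 20, 30), c(10, 20, 30)), -76)
  expect_equal(percent_change(c(4, 4), c(2, 2)), 100)
  expect_identical(percent_change(c(1, 2), c(0, 0)), NA_real_)
})

test_that("r/K classification applies an inclusive CD threshold", {
  expect_equal(classify_strategy(100, 35), "r-strategist")
  expect_equal(classify_strategy(10, 25), "K-strategist")
  expect_equal(classify_strategy(35, 35), "r-strategist")  # boundary is r
  expect_identical(classify_strategy(NA_real_), NA_character_)
})

test_that("impact-factor matrices honour identity, ratio and reciprocal contracts", {
  set.seed(24)
  amended <- activity_table(rand_activity_df(n_resp = 3))

  # identical arms: no biostimulation effect anywhere
  m_id <- compute_if_matrix(amended, amended, baseline_mode = "paired")
  expect_true(all(abs(unclass(m_id) - 1) < 1e-12, na.rm = TRUE))

  # a doubled baseline is inhibition: IF = 0.5 by definition
  baseline <- amended
  baseline$value <- 2 * baseline$value
  m_half <- compute_if_matrix(amended, activity_table(baseline))
  expect_true(all(abs(unclass(m_half) - 0.5) < 1e-12))

  # swapping the two arms inverts every entry
  other <- amended
  other$value <- round(runif(nrow(other), 1, 9), 3)
  m1 <- compute_if_matrix(amended, other)
  m2 <- compute_if_matrix(other, amended)
  expect_equal(unclass(m2), 1 / unclass(m1), tolerance = 1e-12)
})

test_that("impact factors flag missing denominators and support both baselines", {
  grid <- expand.grid(dose = c(0, 50), day = 15, biostimulant = FALSE,
                      replicate = 1:2, KEEP.OUT.ATTRS = FALSE)
  amended <- grid; amended$value <- 6; amended$biostimulant <- TRUE
  base <- grid; base$value <- 3
  base$value[base$dose == 50] <- 0                  # zero baseline cell
  m <- compute_if_matrix(activity_table(amended, response = "Deh"),
                         activity_table(base, response = "Deh"))
  expect_true(is.na(m["Deh", "50|15"]))             # flagged, not Inf
  expect_equal(unname(m["Deh", "0|15"]), 2)

  # control-soil baseline: every cell is divided by the amended dose-0 cell
  df2 <- expand.grid(dose = c(0, 50), day = 15, biostimulant = TRUE,
                     replicate = 1:2, KEEP.OUT.ATTRS = FALSE)
  df2$value <- ifelse(df2$dose == 0, 4, 6)
  cs <- compute_if_matrix(activity_table(df2, response = "Deh"),
                          baseline_mode = "control-soil")
  expect_equal(unname(cs["Deh", "0|15"]), 1)
  expect_equal(unname(cs["Deh", "50|15"]), 1.5)
})

test_that("pooled and per-replicate index tables agree on pooled counts", {
  set.seed(25)
  cfg <- tiny_scenario()
  colonies <- generate_colony_counts(cfg, seed = 7)
  per_rep <- colony_index_table(colonies, pooled = FALSE)
  pooled <- colony_index_table(colonies, pooled = TRUE)
  expect_equal(nrow(per_rep), nrow(colonies))
  # pooled totals are the sum of replicate totals within each cell
  key <- paste(per_rep$group, per_rep$dose, per_rep$day, per_rep$biostimulant)
  sums <- tapply(per_rep$n_total, key, sum)
  pkey <- paste(pooled$group, pooled$dose, pooled$day, pooled$biostimulant)
  expect_equal(as.numeric(sums[pkey]), pooled$n_total)
  expect_true(all(pooled$cd >= 10 & pooled$cd <= 100))
})
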