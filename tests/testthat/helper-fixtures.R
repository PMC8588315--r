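# In-code fixtures shared across test files.

# random valid long-format activity data frame
rand_activity_df <- function(n_resp = 2, doses = c(0, 0.1, 1, 10, 50),
                             days = c(15, 30), reps = 3) {
  grid <- expand.grid(replicate = seq_len(reps), biostimulant = c(FALSE, TRUE),
                      day = days, dose = doses,
                      response = paste0("R", seq_len(n_resp)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$value <- round(stats::runif(nrow(grid), 0.1, 50), 4)
  grid
}

# random valid OTU table; some lineages truncated below a random rank
rand_otu <- function(n_taxa = 12, n_samples = 4, lambda = 60) {
  phyla <- c("Proteobacteria", "Firmicutes", "Actinobacteria", "Bacteroidetes")
  lineage <- data.frame(
    phylum = sample(phyla, n_taxa, replace = TRUE),
    class = paste0("Class", sample(1:3, n_taxa, replace = TRUE)),
    order = paste0("Order", sample(1:3, n_taxa, replace = TRUE)),
    family = paste0("Family", sample(1:4, n_taxa, replace = TRUE)),
    genus = paste0("Genus", sample(1:6, n_taxa, replace = TRUE)),
    stringsAsFactors = FALSE)
  # truncate some lineages: blank every rank from a random depth on
  for (i in seq_len(n_taxa)) {
    depth <- sample(1:5, 1)
    if (depth < 5) lineage[i, seq(depth + 1, 5)] <- ""
  }
  counts <- matrix(stats::rpois(n_taxa * n_samples, lambda) + 1L, n_taxa,
                   dimnames = list(paste0("OTU", seq_len(n_taxa)),
                                   paste0("S", seq_len(n_samples))))
  otu_table(counts, lineage)
}

# random symmetric significance matrix with FALSE diagonal
rand_sig_matrix <- function(n, p = 0.4) {
  m <- matrix(FALSE, n, n)
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2) < p
  m | t(m)
}

# brute-force verifier: does the letter display encode exactly the
# non-significance relation?
cld_encodes_relation <- function(letters_str, sig) {
  n <- length(letters_str)
  sets <- strsplit(letters_str, "")
  if (any(!nzchar(letters_str))) return(FALSE)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      share <- length(intersect(sets[[i]], sets[[j]])) > 0
      if (share == sig[i, j]) return(FALSE)
    }
  }
  TRUE
}

# tiny scenario keeping generated objects small in unit tests
tiny_scenario <- function(replicates = 3) {
  scenario_config(doses = c(0, 10, 50), days = c(15, 30),
                  replicates = replicates)
}
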