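# End-to-end orchestration: generate or load the dataset, compute indices,
# run the inferential layer and the taxa analytics, summarise residue decay,
# and serialise everything as CSV tables plus a JSON manifest. Reports are
# reproducible bit-for-bit from (config, seed).

#' Summarise contaminant-residue decline
#'
#' Per dose and day, percent decline = `100 * (dose - residue) / dose`;
#' dose-0 series carry no percentage (reported as `NA`). The summary row
#' gives the mean and standard deviation of the decline across contaminated
#' doses at the final sampling day.
#'
#' @param residue data frame `dose, day, residue` as from
#'   [generate_residue_series()].
#' @return list with `table` (dose, day, residue, decline_pct) and
#'   `final_day`, `mean_final_decline`, `sd_final_decline`.
#' @export
summarize_residue_decline <- function(residue) {
  stopifnot(all(c("dose", "day", "residue") %in% names(residue)))
  if (any(residue$residue < 0 | residue$residue > residue$dose + 1e-9)) {
    stop_soiltox("residue must lie in [0, dose]", "soiltox_validation_error")
  }
  tab <- residue
  tab$decline_pct <- ifelse(tab$dose > 0,
                            100 * (tab$dose - tab$residue) / tab$dose,
                            NA_real_)
  final_day <- max(tab$day)
  fin <- tab$decline_pct[tab$day == final_day & tab$dose > 0]
  list(table = tab, final_day = final_day,
       mean_final_decline = mean(fin), sd_final_decline = stats::sd(fin))
}

pipeline_log <- function(verbose, stage, n_in, n_out) {
  if (verbose) {
    message(sprintf("[soiltox] %-18s records in: %5d  out: %5d",
                    stage, n_in, n_out))
  }
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config, control = "all"), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a synthetic dataset to a directory in the package's file formats
#'
#' @param data a dataset from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data$colonies, file.path(dir, "colonies.csv"),
                   row.names = FALSE, quote = FALSE)
  write_activity_table(data$enzymes, file.path(dir, "enzymes.csv"))
  write_activity_table(data$microbes, file.path(dir, "microbes.csv"))
  write_otu_table(data$otu, file.path(dir, "otu.tsv"))
  utils::write.csv(data$otu$sample_map, file.path(dir, "sample_map.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data$residue, file.path(dir, "residue.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory holding `colonies.csv`, `enzymes.csv`,
#'   `microbes.csv`, `otu.tsv`, `sample_map.csv`, `residue.csv`.
#' @return a dataset list as from [generate_dataset()] (without config/seed).
#' @export
read_dataset <- function(dir) {
  colonies <- utils::read.csv(file.path(dir, "colonies.csv"),
                              stringsAsFactors = FALSE)
  colonies$biostimulant <- parse_logical_column(colonies$biostimulant,
                                                "biostimulant")
  list(colonies = colonies,
       enzymes = read_activity_table(file.path(dir, "enzymes.csv")),
       microbes = read_activity_table(file.path(dir, "microbes.csv")),
       otu = read_otu_table(file.path(dir, "otu.tsv"),
                            sample_map = file.path(dir, "sample_map.csv")),
       residue = utils::read.csv(file.path(dir, "residue.csv"),
                                 stringsAsFactors = FALSE))
}

letters_for_table <- function(activity, alpha) {
  base <- activity[!activity$biostimulant, , drop = FALSE]
  out <- list()
  for (resp in unique(base$response)) {
    for (d in sort(unique(base$day))) {
      sub <- base[base$response == resp & base$day == d, , drop = FALSE]
      hg <- tukey_hsd(activity_table(sub), alpha = alpha, by = "dose")
      out[[length(out) + 1L]] <-
        data.frame(response = resp, day = d, dose = hg$labels,
                   mean = hg$means, n = hg$n, letters = hg$letters,
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

dose_correlations <- function(activity, alpha) {
  cm <- activity_cell_means(activity)
  cm <- cm[!cm$biostimulant, , drop = FALSE]
  out <- list()
  for (resp in unique(cm$response)) {
    sub <- cm[cm$response == resp, , drop = FALSE]
    res <- tryCatch(
      pearson_dose_correlation(sub$dose, sub$mean, alpha = alpha),
      soiltox_degenerate_error = function(e) {
        list(r = NA_real_, p_value = NA_real_, significant = NA,
             n = nrow(sub))
      })
    out[[length(out) + 1L]] <-
      data.frame(response = resp, r = res$r, p_value = res$p_value,
                 significant = res$significant, n = res$n,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: load or generate the dataset, validate it, compute the
#' CD/EP index tables (per replicate and pooled), impact-factor matrices for
#' both baseline conventions (microbial counts and enzyme activities),
#' Tukey HSD homogeneous groups with letters per response and day, Pearson
#' dose correlations, PCA of the paired IF matrices, rank-wise taxa analytics
#' (aggregation at all five ranks, 1% abundance filter, shared genera,
#' control-vs-top-dose proportion tests per day) and the residue-decline
#' summary. Given `out_dir`, all tables are serialised as CSV plus a JSON
#' manifest; the run is bit-reproducible from `(config, seed)`.
#'
#' @param config a [scenario_config()] (or path to a YAML scenario).
#' @param data_dir `NULL`/`"synthetic"` to generate data, or a directory
#'   written by [write_dataset()].
#' @param out_dir optional output directory for the serialised report.
#' @param seed master RNG seed for generation.
#' @param alpha_tukey family-wise level for the post-hoc letters
#'   (default 0.01).
#' @param alpha_cor level for the dose-correlation flag (default 0.05).
#' @param cd_threshold CD cut-off for [classify_strategy()].
#' @param min_proportion rare-taxon elimination threshold (default 0.01).
#' @param min_diff proportion-difference filter (default 0.01).
#' @param verbose log one line per stage.
#' @return a `run_report` list (see elements in the source); invisibly the
#'   same object when `out_dir` is written.
#' @export
run_pipeline <- function(config = scenario_config(), data_dir = NULL,
                         out_dir = NULL, seed = 1, alpha_tukey = 0.01,
                         alpha_cor = 0.05, cd_threshold = 35,
                         min_proportion = 0.01, min_diff = 0.01,
                         verbose = TRUE) {
  if (is.character(config)) config <- scenario_from_yaml(config)

  if (is.null(data_dir) || identical(data_dir, "synthetic")) {
    data <- generate_dataset(config, seed = seed)
  } else {
    data <- read_dataset(data_dir)
  }
  pipeline_log(verbose, "load/generate", 0L, nrow(data$colonies))

  # indices ------------------------------------------------------------------
  idx_rep <- colony_index_table(data$colonies, pooled = FALSE)
  idx_pool <- colony_index_table(data$colonies, pooled = TRUE)
  idx_pool$strategy <- classify_strategy(idx_pool$cd, cd_threshold)
  pipeline_log(verbose, "indices", nrow(data$colonies), nrow(idx_rep))

  # impact factors: both baseline conventions, on the pre-split arms
  arm <- function(tab, bs) activity_table(tab[tab$biostimulant == bs, ])
  if_mats <- list(
    microbes_paired = compute_if_matrix(arm(data$microbes, TRUE),
                                        arm(data$microbes, FALSE),
                                        baseline_mode = "paired"),
    microbes_control_soil = compute_if_matrix(arm(data$microbes, TRUE),
                                              baseline_mode = "control-soil"),
    enzymes_paired = compute_if_matrix(arm(data$enzymes, TRUE),
                                       arm(data$enzymes, FALSE),
                                       baseline_mode = "paired"),
    enzymes_control_soil = compute_if_matrix(arm(data$enzymes, TRUE),
                                             baseline_mode = "control-soil"))
  pipeline_log(verbose, "impact factors", nrow(data$enzymes),
               sum(vapply(if_mats, length, integer(1))))

  # post-hoc groups and correlations ------------------------------------------
  groupings <- rbind(
    cbind(assay = "microbes", letters_for_table(data$microbes, alpha_tukey)),
    cbind(assay = "enzymes", letters_for_table(data$enzymes, alpha_tukey)))
  correlations <- rbind(
    cbind(assay = "microbes", dose_correlations(data$microbes, alpha_cor)),
    cbind(assay = "enzymes", dose_correlations(data$enzymes, alpha_cor)))
  pipeline_log(verbose, "group stats", nrow(data$enzymes), nrow(groupings))

  # PCA of impact factors; a no-effect IF matrix is constant and carries no
  # variance to decompose, which is reported rather than fatal
  safe_pca <- function(m) {
    tryCatch(pca_if(m, standardized = TRUE),
             soiltox_degenerate_error = function(e) NULL)
  }
  pca <- list(microbes = safe_pca(if_mats$microbes_paired),
              enzymes = safe_pca(if_mats$enzymes_paired))

  # taxa ------------------------------------------------------------------------
  profiles <- lapply(stats::setNames(RANKS, RANKS),
                     function(r) aggregate_rank(data$otu, r))
  filtered <- lapply(profiles, filter_min_proportion,
                     threshold = min_proportion)
  genus_profile <- profiles$genus
  shared <- shared_taxa(genus_profile, min_proportion = min_proportion)

  smap <- data$otu$sample_map
  top_dose <- max(smap$dose)
  taxa_tests <- list()
  dominant <- list()
  for (d in sort(unique(smap$day))) {
    s0 <- smap$sample[smap$dose == 0 & smap$day == d][1]
    s1 <- smap$sample[smap$dose == top_dose & smap$day == d][1]
    if (is.na(s0) || is.na(s1)) next
    key <- paste0("day", d)
    taxa_tests[[key]] <- profile_proportion_tests(genus_profile, s1, s0)
    dominant[[key]] <- dominant_by_difference(genus_profile, s1, s0,
                                              min_diff = min_diff)
  }
  pipeline_log(verbose, "taxa", nrow(data$otu$counts),
               sum(vapply(taxa_tests, nrow, integer(1))))

  # residue ----------------------------------------------------------------------
  residue_summary <- summarize_residue_decline(data$residue)

  report <- structure(list(
    provenance = list(seed = data$seed %||% NA_integer_,
                      config_hash = config_hash(config),
                      package_version = as.character(utils::packageVersion("soiltox")),
                      alpha_tukey = alpha_tukey, alpha_cor = alpha_cor,
                      cd_threshold = cd_threshold,
                      min_proportion = min_proportion, min_diff = min_diff),
    data = data,
    index_tables = list(per_replicate = idx_rep, pooled = idx_pool),
    if_matrices = if_mats,
    groupings = groupings,
    correlations = correlations,
    pca = pca,
    taxa = list(profiles = profiles, filtered = filtered, shared = shared,
                tests = taxa_tests, dominant = dominant),
    residue_summary = residue_summary), class = "run_report")

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  invisible(report)
}

#' Serialise a run report to a directory
#'
#' Writes every result table as CSV, the PCA reports, the shared-taxon set
#' as JSON and a manifest recording seed, config hash, package version and
#' the analysis options; contains no wall-clock information so reruns are
#' byte-identical.
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  w(report$index_tables$per_replicate, "indices_per_replicate.csv")
  w(report$index_tables$pooled, "indices_pooled.csv")
  for (nm in names(report$if_matrices)) {
    write_if_matrix(report$if_matrices[[nm]],
                    file.path(out_dir, paste0("if_", nm, ".csv")))
  }
  w(report$groupings, "homogeneous_groups.csv")
  w(report$correlations, "dose_correlations.csv")
  for (nm in names(report$pca)) {
    if (!is.null(report$pca[[nm]])) {
      write_pca_report(report$pca[[nm]], file.path(out_dir, paste0("pca_", nm)))
    }
  }
  for (nm in names(report$taxa$tests)) {
    w(report$taxa$tests[[nm]], paste0("taxa_tests_", nm, ".csv"))
    w(report$taxa$dominant[[nm]], paste0("taxa_dominant_", nm, ".csv"))
  }
  jsonlite::write_json(report$taxa$shared,
                       file.path(out_dir, "shared_genera.json"))
  w(report$residue_summary$table, "residue_decline.csv")
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
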