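#' Pipeline configuration
#'
#' One object carrying every tunable parameter of the end-to-end analysis,
#' echoed verbatim into the run summary. Input is either a directory of
#' per-run PSM tables plus a design table, or a [simulation_config()] to
#' simulate on the fly (its seed is overridden by `seed`).
#'
#' @param psm_dir directory containing `psm_<run_id>.tsv` files.
#' @param design_path design TSV (required with `psm_dir`).
#' @param sim_config a [simulation_config()] for simulate-on-the-fly mode.
#' @param keep_species species kept after contaminant filtering.
#' @param dave_threshold,dci_threshold DEP-calling thresholds.
#' @param f_min,p_max F-screen retention thresholds.
#' @param min_conditions presence-frequency filter threshold.
#' @param min_support common-trend support; `NULL` = all comparisons of the
#'   BPA family.
#' @param reference_path optional one-symbol-per-line reference protein list
#'   (e.g. known vesicle proteins) for the overlap summary.
#' @param seed integer seed governing every stochastic step.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(psm_dir = NULL, design_path = NULL,
                            sim_config = NULL,
                            keep_species = "human",
                            dave_threshold = 0.2, dci_threshold = 2.0,
                            f_min = 2, p_max = 0.05,
                            min_conditions = 2L, min_support = NULL,
                            reference_path = NULL, seed = 1L) {
  if (is.null(sim_config) && (is.null(psm_dir) || is.null(design_path)))
    stop("provide either sim_config or psm_dir + design_path")
  stopifnot(dave_threshold > 0, dci_threshold > 0, f_min >= 0,
            p_max > 0, p_max <= 1, min_conditions >= 1)
  structure(list(psm_dir = psm_dir, design_path = design_path,
                 sim_config = sim_config, keep_species = keep_species,
                 dave_threshold = dave_threshold, dci_threshold = dci_threshold,
                 f_min = f_min, p_max = p_max,
                 min_conditions = as.integer(min_conditions),
                 min_support = min_support,
                 reference_path = reference_path, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full spectral-count analysis
#'
#' simulate/ingest -> contaminant filter -> aggregate -> normalize -> aPSM ->
#' pairwise DAve/DCI comparisons and common-trend mining -> F screen ->
#' Ward/Euclidean clustering and PCA -> modification-rate statistics ->
#' combined candidate list. All tabular outputs are TSV, the dendrogram is
#' Newick, and a machine-readable `summary.json` plus a parameter-echoing
#' `run_log.txt` are written; the run is deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return invisibly, the summary list with attribute `digest` (md5 of
#'   `summary.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "comparisons"), showWarnings = FALSE)
  log <- c(sprintf("specount pipeline, seed %d", config$seed),
           sprintf("parameters: dave>=%g dci>=%g f>=%g p<=%g min_conditions=%d",
                   config$dave_threshold, config$dci_threshold, config$f_min,
                   config$p_max, config$min_conditions))
  stage <- function(...) log <<- c(log, sprintf(...))

  if (!is.null(config$sim_config)) {
    sc <- config$sim_config
    sc$seed <- config$seed
    sim <- simulate_experiment(sc)
    records <- sim$records
    design <- sim$design
    stage("simulate: %d PSMs over %d runs", nrow(records), nrow(design))
  } else {
    design <- read_design(config$design_path)
    files <- file.path(config$psm_dir, paste0("psm_", design$run_id, ".tsv"))
    missing <- files[!file.exists(files)]
    if (length(missing) > 0)
      stop("ingest: missing PSM table(s): ", paste(head(missing, 3), collapse = ", "))
    records <- data.table::rbindlist(lapply(files, read_psm_table))
    stage("ingest: %d PSMs over %d runs", nrow(records), nrow(design))
  }
  n_total <- nrow(records)

  kept <- suppressMessages(filter_species(records, config$keep_species))
  n_removed <- attr(kept, "n_removed")
  stage("filter_species: removed %d of %d PSMs (%.1f%%)",
        n_removed, n_total, 100 * n_removed / n_total)

  # Runs are aligned on their full identified totals (contaminant included:
  # the serum background is a stable reference shared by all conditions),
  # then quantification proceeds on the kept species only.
  counts_all <- aggregate_counts(records, design)
  norm_all <- normalize_runs(counts_all)
  sp <- attr(counts_all, "species")
  keep_rows <- rownames(counts_all)[sp[rownames(counts_all)] == config$keep_species]
  counts <- count_matrix(unclass(counts_all)[keep_rows, , drop = FALSE],
                         kind = "run")
  write_count_matrix(counts, file.path(out_dir, "counts_run.tsv"))
  norm <- count_matrix(unclass(norm_all)[keep_rows, , drop = FALSE],
                       kind = "run")
  write_count_matrix(norm, file.path(out_dir, "counts_norm.tsv"))
  apsm <- average_condition(norm, design)
  write_count_matrix(apsm, file.path(out_dir, "apsm.tsv"))
  stage("quantify: %d proteins x %d runs -> %d conditions",
        nrow(counts), ncol(counts), ncol(apsm))

  freq_prot <- frequency_filter(apsm, config$min_conditions)
  stage("frequency_filter: %d of %d proteins in >= %d conditions",
        length(freq_prot), nrow(apsm), config$min_conditions)

  rep_tech <- repeatability_r2(norm, design, "technical")
  rep_bio <- repeatability_r2(norm, design, "biological")
  stage("repeatability: technical R2 %.4f (sd %.4f), biological %.4f (sd %.4f)",
        rep_tech$mean_r2, rep_tech$sd_r2, rep_bio$mean_r2, rep_bio$sd_r2)

  specs <- comparison_family(design, config$dave_threshold, config$dci_threshold)
  calls <- lapply(specs, function(s) compare_conditions(apsm, s))
  for (nm in names(calls)) {
    out <- calls[[nm]]
    out$dave <- round(out$dave, 2) # display precision; internals keep full
    data.table::fwrite(out, file.path(out_dir, "comparisons",
                                      paste0(gsub("[^A-Za-z0-9._+-]", "_", nm), ".tsv")),
                       sep = "\t")
  }
  deps_per <- vapply(calls, function(cc) sum(cc$is_dep), integer(1))
  dep_union <- sort(unique(unlist(lapply(calls, function(cc) cc$protein[cc$is_dep]))))
  bpa_family <- calls[grepl("^BPA\\+_vs_BPA-", names(calls))]
  trend <- if (length(bpa_family) >= 2)
    common_trend(bpa_family, config$min_support %||% length(bpa_family))
  else list(up_in_X = character(0), up_in_Y = character(0))
  trend_dt <- data.table::data.table(
    protein = c(trend$up_in_X, trend$up_in_Y),
    trend = rep(c("up_in_BPA+", "up_in_BPA-"),
                c(length(trend$up_in_X), length(trend$up_in_Y))))
  data.table::fwrite(trend_dt, file.path(out_dir, "common_trend.tsv"), sep = "\t")
  stage("maproma: %d comparisons, %d DEPs (union), common trend %d up / %d down in BPA+",
        length(calls), length(dep_union),
        length(trend$up_in_X), length(trend$up_in_Y))

  screen <- f_screen(norm, design, f_min = config$f_min, p_max = config$p_max)
  data.table::fwrite(screen, file.path(out_dir, "screen.tsv"), sep = "\t")
  retained <- screen$protein[screen$retained]
  stage("f_screen: retained %d of %d proteins", length(retained), nrow(screen))

  if (length(retained) >= 1) {
    hc <- cluster_profiles(norm[retained, , drop = FALSE])
    write_newick(hc, file.path(out_dir, "dendrogram.nwk"))
    write_count_matrix(
      count_matrix(unclass(norm)[retained, , drop = FALSE], kind = "run"),
      file.path(out_dir, "heatmap_matrix.tsv"))
  } else hc <- NULL

  pca <- pca_profiles(apsm)
  sc_dt <- data.table::data.table(condition = rownames(pca$scores))
  sc_dt <- cbind(sc_dt, data.table::as.data.table(pca$scores))
  data.table::fwrite(sc_dt, file.path(out_dir, "pca_scores.tsv"), sep = "\t")
  stage("pca: PC1 %.1f%%, PC2 %.1f%% of variance",
        100 * pca$explained[1], 100 * pca$explained[2])

  ptm <- rbind(
    ptm_rate(kept, "Met"), ptm_rate(kept, "Tyr"),
    ptm_rate(kept, "Met", design, by = "condition"),
    ptm_rate(kept, "Tyr", design, by = "condition"))
  data.table::fwrite(ptm, file.path(out_dir, "ptm_rates.tsv"), sep = "\t")
  ctr <- contribution_ratio(ptm_rate(kept, "Met"), ptm_rate(kept, "Tyr"))
  ptm_contrasts <- ptm_dose_contrasts(kept, design)
  stage("ptm: Met rate %.4f, Tyr rate %.4f, Met:Tyr contribution %.2f",
        ptm$rate[1], ptm$rate[2], ctr)

  combined <- combine_selections(retained, dep_union)
  data.table::fwrite(combined, file.path(out_dir, "combined_selection.tsv"), sep = "\t")

  overlap <- NULL
  if (!is.null(config$reference_path) && length(freq_prot) > 0) {
    ref <- readLines(config$reference_path)
    overlap <- overlap_percent(freq_prot, ref)
    stage("overlap: %.1f%% of frequency-filtered proteins in reference", overlap)
  }

  summary <- list(
    seed = config$seed,
    n_runs = ncol(counts), n_conditions = ncol(apsm),
    n_psms_total = n_total, n_psms_removed = n_removed,
    removed_fraction_percent = 100 * n_removed / n_total,
    n_proteins = nrow(counts),
    n_frequency_filtered = length(freq_prot),
    repeatability = list(
      technical = list(mean_r2 = rep_tech$mean_r2, sd_r2 = rep_tech$sd_r2),
      biological = list(mean_r2 = rep_bio$mean_r2, sd_r2 = rep_bio$sd_r2)),
    n_comparisons = length(calls),
    deps_per_comparison = as.list(deps_per),
    n_deps_union = length(dep_union),
    common_trend = trend,
    n_screen_retained = length(retained),
    n_combined = nrow(combined),
    pca_explained = pca$explained,
    ptm = list(met_rate = ptm$rate[1], tyr_rate = ptm$rate[2],
               met_tyr_contribution = ctr, dose_contrasts = ptm_contrasts),
    overlap_percent = overlap,
    parameters = config[c("keep_species", "dave_threshold", "dci_threshold",
                          "f_min", "p_max", "min_conditions")]
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log, file.path(out_dir, "run_log.txt"))
  attr(summary, "digest") <- unname(tools::md5sum(file.path(out_dir, "summary.json")))
  invisible(summary)
}

# Met-oxidation rate contrasts between the no-dose and highest-dose
# conditions at each harvest time (runs pooled over the two arms).
ptm_dose_contrasts <- function(records, design) {
  doses <- sort(unique(design$dose_gy))
  if (length(doses) < 2) return(list())
  lo <- min(doses); hi <- max(doses)
  out <- list()
  for (h in sort(unique(design$harvest_h))) {
    runs_lo <- design$run_id[design$dose_gy == lo & design$harvest_h == h]
    runs_hi <- design$run_id[design$dose_gy == hi & design$harvest_h == h]
    if (length(runs_lo) == 0 || length(runs_hi) == 0) next
    a <- ptm_rate(records[records$run_id %in% runs_lo, ], "Met",
                  scope = sprintf("%sGy_%sh", lo, h))
    b <- ptm_rate(records[records$run_id %in% runs_hi, ], "Met",
                  scope = sprintf("%sGy_%sh", hi, h))
    if (a$containing_psms == 0 || b$containing_psms == 0) next
    out[[sprintf("met_%sGy_vs_%sGy_%sh", lo, hi, h)]] <-
      list(rate_low = a$rate, rate_high = b$rate,
           p_value = compare_rates(a, b))
  }
  out
}
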