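# Hand-built PSM records with valid defaults
make_records <- function(n = 3,
                         run_id = "r1",
                         protein_accession = paste0("P", seq_len(n)),
                         species = "human",
                         gene_symbol = "",
                         peptide = "ACDMYEK",
                         met_oxidized = FALSE,
                         tyr_nitrosylated = FALSE) {
  data.frame(run_id = rep_len(run_id, n),
             protein_accession = rep_len(protein_accession, n),
             species = rep_len(species, n),
             gene_symbol = rep_len(gene_symbol, n),
             peptide = rep_len(peptide, n),
             met_oxidized = rep_len(met_oxidized, n),
             tyr_nitrosylated = rep_len(tyr_nitrosylated, n),
             stringsAsFactors = FALSE)
}

# A two-run design with arbitrary run ids (single condition cell)
toy_design <- function(run_ids, bpa = "minus", dose = 0, harvest = 6) {
  n <- length(run_ids)
  data.frame(run_id = run_ids, bpa = rep_len(bpa, n),
             dose_gy = rep_len(dose, n),
             irradiation_min = rep_len(ifelse(dose == 0, 0, 60), n),
             harvest_h = rep_len(harvest, n),
             biorep = rep_len(1L, n), techrep = seq_len(n),
             stringsAsFactors = FALSE)
}

# Small, fast simulator settings for unit tests
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_human_proteins = 80L, n_bovine_proteins = 8L,
                   depth_per_run = 1500, n_dep = 8L, seed = 42L)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

# Records with exact modified/containing counts per residue
ptm_fixture <- function(n_met, n_met_mod, n_tyr, n_tyr_mod, run_id = "r1") {
  met <- make_records(n_met, run_id = run_id, peptide = "ACDMEFK",
                      met_oxidized = seq_len(n_met) <= n_met_mod)
  tyr <- make_records(n_tyr, run_id = run_id, peptide = "ACDYEFK",
                      tyr_nitrosylated = seq_len(n_tyr) <= n_tyr_mod)
  rbind(met, tyr)
}

# --- independent oracles -----------------------------------------------------

# literal per-protein evaluation of the printed index formulas + thresholds
oracle_dep_calls <- function(apsm, xcond, ycond, dave_t = 0.2, dci_t = 2) {
  out <- list()
  for (p in rownames(apsm)) {
    X <- apsm[p, xcond]; Y <- apsm[p, ycond]
    if (X == 0 && Y == 0) next
    dave <- if (X + Y == 0) 0 else ((X - Y) / (X + Y)) / 0.5
    dci <- (X + Y) * (X - Y) / 2
    out[[p]] <- data.frame(
      protein = p, dave = dave, dci = dci,
      is_dep = abs(dave) >= dave_t & abs(dci) >= dci_t,
      direction = if (dave > 0) "up_in_X" else if (dave < 0) "up_in_Y" else "none",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, unname(out))
}

# one-way ANOVA through stats::aov, independent of the vectorized screen
oracle_anova <- function(values, groups) {
  fit <- summary(stats::aov(values ~ factor(groups)))[[1]]
  c(f = fit[["F value"]][1], p = fit[["Pr(>F)"]][1])
}

# greedy Ward agglomeration by direct within-cluster sum-of-squares increase;
# returns merge heights (sqrt(2 * ESS increase)) and the final 2-cluster split
oracle_ward <- function(X) {
  cl <- lapply(seq_len(ncol(X)), function(i) i)
  ess <- function(idx) {
    M <- X[, idx, drop = FALSE]
    sum((M - rowMeans(M))^2)
  }
  heights <- numeric(0)
  split2 <- NULL
  while (length(cl) > 1) {
    best <- NULL; bestd <- Inf
    for (i in 1:(length(cl) - 1)) for (j in (i + 1):length(cl)) {
      d <- ess(c(cl[[i]], cl[[j]])) - ess(cl[[i]]) - ess(cl[[j]])
      if (d < bestd) { bestd <- d; best <- c(i, j) }
    }
    if (length(cl) == 2) split2 <- lapply(cl, function(ix) sort(colnames(X)[ix]))
    heights <- c(heights, sqrt(2 * bestd))
    cl[[best[1]]] <- c(cl[[best[1]]], cl[[best[2]]])
    cl[[best[2]]] <- NULL
  }
  list(heights = heights, split2 = split2)
}
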