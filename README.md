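# specount

Label-free spectral-count proteomics for extracellular-vesicle (EV)
experiments contaminated by fetal bovine serum, built around a two-arm,
multi-dose, multi-timepoint radiobiology design (12 conditions × 3
biological replicates × 2 technical runs = 72 LC-MS/MS runs).

The package is aimed at proteomics analysts who start from *identified* PSM
tables (one row per peptide-spectrum match, after database search, FDR
control and protein inference) and need the downstream quantification and
mining: two-species contaminant filtering, normalization, condition
averaging, differential calling, multivariate structure, and
residue-modification statistics. A PSM-level simulator with machine-readable
ground truth makes every stage testable.

## The statistics at the core

**Quantification.** A protein's abundance proxy in a run is its PSM count.
Runs are aligned by total-count scaling to the mean run total, and the aPSM
(average PSM) of a protein in a condition is the mean of its normalized
counts over the condition's replicate runs.

**Differential indexes.** For a pairwise comparison with condition averages
X and Y, per protein:

    DAve = (X − Y)/(X + Y)/0.5        (bounded fold-change index in [−2, 2])
    DCI  = (X + Y)(X − Y)/2           (abundance-weighted confidence index)

A protein is a differentially expressed protein (DEP) when |DAve| ≥ 0.2 and
|DCI| ≥ 2 jointly; a planted fold change f corresponds to an expected
DAve of 2(f−1)/(f+1). Families of comparisons (treated vs untreated at
matched dose/time; high vs lower dose within the treated arm) are mined for
proteins with a consistent direction (`common_trend()`).

**Variable screen and structure.** Per protein, a one-way ANOVA F ratio
(model mean square / error mean square) over the run profiles with retention
at F ≥ 2 and p ≤ 0.05; retained profiles go to Ward/Euclidean hierarchical
clustering (Newick export) and condition-level PCA.

**Modification rates.** Met-oxidation and Tyr-nitrosylation occupancy at the
PSM level: modified PSMs / residue-containing PSMs, per condition or pooled,
compared between conditions with a two-proportion test (exact-test option).

## Worked example

Simulate the full 72-run design at its default conditions (1000 human
proteins, 60% bovine PSM mass led by an albumin-like contaminant, 20,000
PSMs/run, 50 planted proteins at fold 2 in the treated arm) and run the
whole pipeline:

```r
library(specount)
cfg <- simulation_config(seed = 1)
out <- run_pipeline(pipeline_config(sim_config = cfg, seed = 1), "specount_out")
```

which prints to `summary.json`/`run_log.txt` (values from this exact call):

```
runs: 72   conditions: 12   comparisons: 10
PSMs: 1458375   bovine removed: 59.3%
tech R2: 0.8824   bio R2: 0.8618
screen retained: 62   DEP union: 783   combined: 786
common trend: up in BPA+ 38 | up in BPA- 0
PC1 explains 40.6%
Met rate: 0.123   Tyr rate: 0.1033
met_0Gy_vs_11.3Gy_6h :  0.1151 -> 0.1374 , p = 8e-26
met_0Gy_vs_11.3Gy_24h : 0.117  -> 0.1381 , p = 4.4e-23
```

Reading this: the 72 runs collapse to 12 condition profiles and 10 canonical
pairwise comparisons; ~59% of spectra were bovine contaminants and were
excluded from quantification; technical repeatability (mean R² over 36
technical pairs) exceeds biological repeatability, as it should; the F
screen retains 62 discriminating proteins; 38 proteins are DEPs up in the
treated arm in *all six* matched comparisons (the planted, well-expressed
effects); PCA separates the arms along PC1; and the Met-oxidation rate rises
from ~11.5% to ~13.7% at the highest dose, while Tyr stays flat. Single
proteins are inspected per comparison in `specount_out/comparisons/*.tsv`,
e.g. `dave(3, 1)` = 1.0 and `dci(3, 1)` = 4.0 for a protein with aPSM 3
vs 1.

A shell entry point with subcommands (`simulate`, `ingest`, `normalize`,
`compare`, `screen`, `cluster`, `pca`, `ptm`, `all`) wraps the same
functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/specount.R", package="specount"))')" all --seed 1 --out specount_out
```

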