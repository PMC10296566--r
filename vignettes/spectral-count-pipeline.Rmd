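---
title: "Label-free spectral-count analysis of serum-contaminated EV proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free spectral-count analysis of serum-contaminated EV proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(specount)
```

## The analysis problem

Shotgun proteomics of extracellular vesicles (EVs) harvested from cell
culture media faces two structural difficulties. First, quantification is
label-free: the abundance proxy for a protein in a run is its spectral
count, the number of peptide-spectrum matches (PSMs) assigned to it. Second,
serum-conditioned media contaminate the preparation with bovine serum
proteins — chiefly albumin — which dominate the PSM budget and compress the
dynamic range available to the human proteome of interest.

`specount` implements the complete downstream analysis for a two-arm
radiobiology design of this kind: 12 conditions (with/without a boron
carrier × three neutron doses, 0/1.9/11.3 Gy, × two EV harvest times,
6/24 h), each with 3 biological replicates run in technical duplicate — 72
runs in all. The pipeline starts from identified PSM tables (database
search, FDR control and protein inference happen upstream and are out of
scope) and covers:

1. two-species contaminant handling (species from FASTA pair, filtering);
2. total-count normalization and condition averaging into aPSM profiles;
3. differential calling with the paired indexes DAve and DCI;
4. per-protein F-ratio screening, Ward/Euclidean clustering and PCA;
5. residue-modification (Met oxidation, Tyr nitrosylation) rate statistics;
6. a PSM-level simulator with machine-readable ground truth that emulates
   the full design, so every stage is testable against planted truth.

## Quantification model

For a protein $p$ in run $r$, the raw quantity is the PSM count $c_{pr}$.
Runs are aligned by total-count scaling: each run column is multiplied by
$\bar T / T_r$, where $T_r$ is the run total and $\bar T$ the mean total, so
every run carries the same number of (rescaled) spectra. This is the minimal
defensible normalization for spectral counts; it is isolated in
`normalize_runs()` so an alternative can be swapped in. When a contaminant
species is present, the pipeline computes the scale factors from the *full*
two-species totals and only then restricts to the kept species: the serum
background is condition-independent and therefore the most stable alignment
reference, and this choice keeps genuine treatment-induced shifts of the
human PSM budget from leaking into every protein's profile.

The aPSM of protein $p$ in condition $c$ is the arithmetic mean of its
normalized counts over all 6 runs of the condition (`average_condition()`;
a nested tech-then-bio mean is available and identical for balanced
designs).

## Differential indexes

For one pairwise comparison with condition averages $X$ and $Y$:

$$\mathrm{DAve} = \frac{(X - Y)}{(X + Y)}\Big/ 0.5 = \frac{2(X-Y)}{X+Y},
\qquad \mathrm{DCI} = \frac{(X+Y)(X-Y)}{2}.$$

DAve is a bounded fold-change index in $[-2, 2]$: a protein absent from one
side sits exactly at $\pm 2$, and a fold change $f$ corresponds to
$\mathrm{DAve} = 2(f-1)/(f+1)$ (`expected_dave()`), so the conventional
threshold 0.2 is a $\sim$1.22-fold change. DCI weights the same difference
by total abundance and guards against calls on proteins observed a handful
of times. A protein is a DEP when $|\mathrm{DAve}| \ge 0.2$ **and**
$|\mathrm{DCI}| \ge 2$ jointly — the stricter of the two readings of how the
two thresholds combine; both cutoffs are exposed (`--dave-threshold`,
`--dci-threshold`) so a DAve-only analysis is one flag away. When
$X = Y = 0$ both indexes are defined as 0 and the protein is never called:
absence on both sides is no evidence. Outputs print DAve to two decimals,
mirroring common reporting practice; internal precision is full.

`comparison_family()` enumerates the canonical contrasts of the design: the
six treated-vs-untreated comparisons at matched dose and time, and within
the treated arm the four contrasts of the highest dose against each lower
dose at each harvest time. `common_trend()` then mines a family for proteins
that are DEPs with the same sign in at least `min_support` comparisons
(default: all of them — the "always up/down" set).

## The F-ratio screen, clustering and PCA

The variable screen fits, per protein, a one-way between-group ANOVA over
the run profiles: $F$ = model mean square / error mean square on
$(g-1,\,N-g)$ degrees of freedom, with the upper-tail F p-value. Retention
requires $F \ge 2$ and $p \le 0.05$ (both configurable). The default
grouping is the 12 condition cells over 72 runs ($df = 11, 60$); the
grouping variable is an explicit argument because coarser factorizations
(e.g. arm only) are equally legitimate. P-values are deliberately not
multiplicity-adjusted by default — the screen is a ranking device, not an
inference — but a Benjamini–Hochberg option exists. Degenerate rows are
defined away from NaN: no variance at all gives $F=0, p=1$; perfect
separation with zero within-group variance gives $F=\infty, p=0$ and is
retained. A discriminant-axis projection (`discriminant_projection()`) is
provided purely as a diagnostic; retention itself is the univariate screen.

Retained profiles are clustered agglomeratively with Euclidean distance and
Ward's minimum-variance criterion (`ward.D2`; merge heights equal
$\sqrt{2\,\Delta\mathrm{ESS}}$). Columns are sorted lexicographically before
clustering so that ties break deterministically, and the dendrogram exports
to Newick. PCA operates on the condition-level aPSM matrix with proteins
row-centred; scores, loadings and explained-variance fractions are
returned, and reconstruction from all components reproduces the centred
input to numerical precision.

## Modification-rate statistics

Modification occupancy is measured at the spectrum level: for a residue
(Met or Tyr), the rate is (PSMs flagged modified) / (PSMs whose peptide
contains the residue), pooled or per condition. In serum-contaminated EV
data both rates typically land near 10–11%, with Met oxidation carrying
roughly five-fold more events than Tyr nitrosylation; `ptm_rate()` and
`contribution_ratio()` reproduce exactly this arithmetic from any PSM table.
Rates are compared between conditions with a two-proportion z-test with
continuity correction (`compare_rates()`); an exact Fisher option exists for
small counts. The identity "pooled rate = count-weighted mean of
per-condition rates" holds exactly and is property-tested.

## What the simulator emulates — and what it does not

`simulate_experiment()` draws PSM-level data with the design's full
structure. Its defaults are the study conditions the rest of the package is
tested under, chosen once and documented here:

| parameter | default | rationale |
|---|---|---|
| `n_human_proteins` | 1000 | order of magnitude of an EV identification list |
| `contaminant_psm_fraction` | 0.6 | serum dominates the PSM budget; one albumin-like protein carries half the contaminant mass |
| `n_bovine_proteins` | 50 | a small serum proteome behind the albumin peak |
| `base_abundance_log_sd` | 1 | ~2 orders of magnitude of abundance across proteins |
| `depth_per_run` | 20,000 | PSMs per LC-MS/MS run |
| `dispersion` | 0.005 | technical spectral-count noise is near-Poisson; resampling is the only technical-replicate noise |
| `bio_sd` | 0.2 | ~20% culture-to-culture CV; drawn per protein × replicate batch |
| `n_dep`, `dep_fold` | 50, 2 | planted treated-arm effects; fold 2 implies expected DAve 2/3 |
| `met_ox_rate`, `tyr_no2_rate` | 0.115, 0.103 | the 10–11% occupancy regime |
| `met_ox_rate_high_dose` | 0.135 | a modest oxidative bump at 11.3 Gy, detectable only weakly at realistic counts |

Counts are negative binomial around *relative abundance × species budget ×
planted effect × batch jitter* (Poisson when `dispersion = 0`). Two
calibration choices deserve explanation:

* **Technical vs biological noise.** Averaging the two technical runs of a
  biological replicate halves the counting variance, so biological
  repeatability can only fall below technical repeatability if the
  biological jitter exceeds that saved variance. At 20,000 PSMs/run a 10%
  jitter does not — it takes roughly 16% before the ordering flips — so the
  default biological CV is 20%, a realistic figure for independent culture
  batches. With it, simulated technical R² exceeds biological R² (e.g.
  0.88 vs 0.86 at seed 1), reproducing the ordering seen in real
  repeatability analyses of this design.
* **Batch structure.** The three biological replicates are modelled as
  replicate experiment batches: one jitter draw per protein × batch, shared
  by all 12 conditions of that batch. This mirrors a split-batch design and
  means batch noise cancels in matched-condition comparisons, exactly as it
  does in the assay.

Peptides are synthetic tryptic-like strings (length 7–20, K/R terminal)
drawn once per protein into a fixed repertoire of 30, with Met and Tyr each
present in half the repertoire; modification flags are Bernoulli at the
condition's rate. The simulator does **not** model chromatography, spectra,
ion intensities, search scoring, FDR, shared peptides or protein grouping —
so passing recovery tests demonstrates that the *statistics* behave as
designed on data with this count structure, not that the upstream
identification pipeline is error-free.

The emitted ground truth records the planted proteins, their folds and
expected DAve, expected per-run counts, and the per-condition modification
rates, which is what the test suite scores recovery against: on the default
conditions, the pooled-arm DAve of planted proteins matches $2(f-1)/(f+1)$
within ±0.1, all well-expressed planted proteins (expected aPSM ≥ 5) are
called at thresholds (0.2, 2) while under 5% of expressed null proteins
are, and Ward clustering and PCA separate the arms at the top split.

## Numerical and degenerate-input conventions

* Zero-variance proteins in the screen: see above; the within/between sums
  of squares are compared against a relative tolerance of $10^{-12}$.
* `normalize_runs()` refuses all-zero run columns by name; it is idempotent
  to $10^{-9}$.
* R² is the squared Pearson correlation of the two count vectors over the
  union of proteins with zeros filled — exactly symmetric in the pair. Raw
  counts are used (no log transform); the choice is recorded in the output
  object.
* Presence for the frequency filter means aPSM > 0 — any evidence counts.
* Species resolution requires each accession in exactly one FASTA;
  ambiguity is an error rather than a guess, because grouping/parsimony
  belongs upstream.
* All randomness flows from a single integer seed; identical seed + config
  gives byte-identical simulator output and pipeline summaries.

## Scaling of the shipped checks

The package's own test suite exercises the full 72-run design throughout,
with the proteome and depth scaled down (≈100–200 proteins, 400–6,000
PSMs/run) in unit tests, and the complete default conditions (1000
proteins, 20,000 PSMs/run, 20 seeds) in the recovery battery. These sizes
are the package's choice of a thorough-but-quick default; all of them are
ordinary parameters that scale up without code changes.

## Known limitations

* Spectral counting saturates for very abundant proteins in real data; the
  simulator does not reproduce saturation, so planted folds translate to
  counts more faithfully than an instrument would.
* DAve/DCI carry no error model and no p-value (by design, as in the
  original index definitions); the F screen's p-values are raw unless BH is
  requested.
* The two-proportion test treats PSMs as independent Bernoulli trials;
  within-peptide correlation of modification states is not modelled.
* `overlap_percent()` compares identifier sets verbatim — mapping
  accessions to gene symbols, where needed, is the caller's concern.
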