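Package: specount
Title: Label-Free Spectral-Count Proteomics with Differential Expression
    Indexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Label-free quantification of shotgun proteomics experiments by
    spectral counting, built for extracellular-vesicle studies where fetal
    bovine serum contaminates the sample. Provides a peptide-spectrum-match
    (PSM) level simulator with a machine-readable ground truth, two-species
    contaminant filtering, total-count normalization and condition averaging
    (aPSM), the MAProMa differential indexes DAve and DCI with joint-threshold
    DEP calling and common-trend mining, per-protein one-way ANOVA F-ratio
    screening with Ward/Euclidean hierarchical clustering and PCA, and
    residue-level modification-rate statistics for methionine oxidation and
    tyrosine nitrosylation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
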