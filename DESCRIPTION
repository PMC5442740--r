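Package: itraqdep
Title: Differential Protein Expression from 4-Plex iTRAQ Reporter-Ion Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting differentially expressed proteins
    (DEPs) from 4-plex iTRAQ reporter-ion quantitation in a two-timepoint,
    two-condition transplantation design: target-decoy FDR filtering of
    peptide-spectrum matches, quantile normalization of reporter intensities,
    L1 (median) aggregation of peptide ratios to protein relative abundances,
    time-resolved DEP selection by one- and two-sample t tests with adaptive
    90th-percentile fold-change cutoffs, and hypergeometric enrichment of DEP
    lists against gene-set collections and neuron/astrocyte/oligodendrocyte
    marker sets. Includes a seeded synthetic-data generator with planted
    protein-level fold-changes and planted cell-type enrichment for end-to-end
    validation against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    purrr,
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
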