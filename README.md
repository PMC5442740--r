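# itraqdep

Differential protein expression from 4-plex iTRAQ reporter-ion data, for
proteomics analysts working with two-condition, two-timepoint isobaric
labeling designs — e.g. comparing treated and vehicle brain tissue at 1 day
and 2 months after a stem-cell transplantation, in triplicate.

The pipeline covers, as tested R functions:

1. **Target-decoy PSM filtering** — at every score threshold *s*,
   FDR(*s*) = #decoys(≥ *s*) / max(1, #targets(≥ *s*)), converted to
   q-values (monotone in score); targets with q < 0.01 are retained.
2. **Quantification** — joint quantile normalization of the 4 channels × 3
   replicates on the log2 scale; per-peptide treatment/vehicle log2 ratios
   at 1 day (116:114) and 2 months (117:115); peptide-to-protein roll-up by
   the L1 optimum, argmin_ρ Σᵢ |rᵢ − ρ| (the median closed form of the
   linear program), with shared peptides excluded.
3. **DEP selection** — per timepoint: two-sided one-sample t test on the
   replicate log2 abundances, ≥ 2 nonredundant peptides, and fold-change
   magnitude 2^|mean log2fc| above the adaptive 90th-percentile cutoff of
   the all-protein fold-change distribution. The late-change class
   (2 months / 1 day) is selected among the 2-month DEPs by a two-sample t
   test and a 90th-percentile cutoff on the normalized fold-change, so it
   is contained in the 2-month class by construction.
4. **Enrichment** — upper-tail hypergeometric over-representation,
   P(X ≥ k), X ~ Hypergeom(N, K, n), of each DEP class × direction against
   GMT gene sets (pass: p < 0.1, overlap ≥ 3) and against neuron /
   astrocyte / oligodendrocyte marker sets (reference p = 0.05), with the
   quantified proteins as background universe.
5. **Synthetic data** — a seeded generator planting known log2
   fold-changes, decoy PSMs, channel bias, and an oligodendrocyte-enriched
   up-regulated 2-month signal, so every stage is validated against ground
   truth.

See `vignettes/itraq-dep-workflow.Rmd` for the full methods account.

## Worked example

The numbered scripts under `analysis/` run the stages in order on the
default simulated dataset (1,000 proteins, 10% planted ±1 log2
fold-changes per timepoint, 5–10 peptides/protein, triplicate):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_filter_psms.R
Rscript analysis/03_quantify.R
Rscript analysis/04_select_deps.R
Rscript analysis/05_enrichment.R
```

which prints (abridged):

```
simulated 28069 PSMs (5614 decoys) over 1000 proteins, 3 replicates
planted DEPs: 100 at 1 day, 100 at 2 months
21139 of 28069 PSMs pass q < 0.01 (22455 targets total, 5614 decoys rejected)
quantified 1000 proteins across 3 replicates
DEPs: 100 at 1 day, 100 at 2 months, 47 late-change (2m/1d)
adaptive cutoffs: 1.27-fold (1 day), 1.22-fold (2 months), 2.01 (normalized)
is_dep_1day: sensitivity 1.000, FDP 0.000
is_dep_2month: sensitivity 1.000, FDP 0.000
containment holds: every late-change DEP is a 2-month DEP

cell-type attribution of up-regulated 2-month DEPs:
  oligodendrocyte  overlap 26  p = 5.52e-16  -log10(p) = 15.26
  neuron           overlap  1  p = 0.994  -log10(p) = 0.00
  astrocyte        overlap  0  p = 1  -log10(p) = -0.00
```

Reading: all 100 planted DEPs per timepoint are recovered with no false
calls; the adaptive fold-change cutoffs land near the bulk of the null
distribution (1.2–1.3-fold); and the planted oligodendrocyte
over-representation among up-regulated 2-month DEPs is attributed to the
right cell type while neuron and astrocyte sets stay at p ≈ 1. Equivalent
in R:

```r
library(itraqdep)
res <- run_pipeline(pipeline_config(sim = simulation_config(seed = 1)))
res$report$counts
res$celltype
```

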