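#!/usr/bin/env Rscript
# Stage 4: differential expression calling.
#
# Calls the three DEP classes: one-sample t tests on the replicate log2
# abundances at each timepoint with an adaptive 90th-percentile fold-change
# cutoff and a two-nonredundant-peptide support rule, then the late-change
# class (2 months / 1 day) among 2-month DEPs via a two-sample t test and a
# 90th-percentile cutoff on the normalized fold-change. Sensitivity and
# false discovery proportion are reported against the planted truth.

suppressMessages(library(itraqdep))

ratios <- read_table_tsv("results/sim/protein_ratios.tsv")
truth <- read_truth("results/sim/truth.tsv")

deps <- select_deps(ratios, selection_thresholds(), incomplete = "drop")
write_table_tsv(deps, "results/sim/deps.tsv")

cat(sprintf("DEPs: %d at 1 day, %d at 2 months, %d late-change (2m/1d)\n",
            sum(deps$is_dep_1day), sum(deps$is_dep_2month),
            sum(deps$is_dep_2m_over_1d)))
cat(sprintf("adaptive cutoffs: %.2f-fold (1 day), %.2f-fold (2 months), %.2f (normalized)\n",
            attr(deps, "fc_cutoff_1day"), attr(deps, "fc_cutoff_2month"),
            attr(deps, "norm_fc_cutoff")))

m <- merge(deps, truth, by.x = "protein", by.y = "protein_id",
           suffixes = c("", "_true"))
for (cls in c("is_dep_1day", "is_dep_2month")) {
  sens <- sum(m[[cls]] & m[[paste0(cls, "_true")]]) / sum(m[[paste0(cls, "_true")]])
  fdp <- sum(m[[cls]] & !m[[paste0(cls, "_true")]]) / max(1, sum(m[[cls]]))
  cat(sprintf("%s: sensitivity %.3f, FDP %.3f\n", cls, sens, fdp))
}
stopifnot(all(deps$is_dep_2month[deps$is_dep_2m_over_1d]))
cat("containment holds: every late-change DEP is a 2-month DEP\n")
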