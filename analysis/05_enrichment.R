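#!/usr/bin/env Rscript
# Stage 5: gene-set and cell-type enrichment.
#
# Hypergeometric over-representation of each DEP class x direction against
# the pathway-style sets (pass rule: p < 0.1 and >= 3 DEPs) and against the
# neuron / astrocyte / oligodendrocyte marker sets (reference line p = 0.05),
# with the quantified proteins as the background universe.

suppressMessages(library(itraqdep))

deps <- read_table_tsv("results/sim/deps.tsv")
# background universe = all quantified proteins (CPDB-style correction)
gene_sets <- read_gmt("results/sim/gene_sets.gmt", universe = deps$protein)

enrichment <- enrich_sets(deps, gene_sets, p_cut = 0.1, min_overlap = 3L)
celltype <- cell_type_profile(deps, gene_sets, p_cut = 0.05)
write_table_tsv(enrichment, "results/sim/enrichment.tsv")
write_table_tsv(celltype, "results/sim/celltype_profile.tsv")

cat(sprintf("%d set x class x direction combinations pass (p < 0.1, overlap >= 3)\n",
            sum(enrichment$passes)))
cat("\ncell-type attribution of up-regulated 2-month DEPs:\n")
up2m <- celltype[celltype$class == "2month" & celltype$direction == "up", ]
for (i in seq_len(nrow(up2m))) {
  cat(sprintf("  %-16s overlap %2d  p = %.3g  -log10(p) = %.2f\n",
              up2m$set_name[i], up2m$overlap_count[i], up2m$p_value[i],
              up2m$neg_log10_p[i]))
}
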