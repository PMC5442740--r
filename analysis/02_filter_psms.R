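#!/usr/bin/env Rscript
# Stage 2: target-decoy FDR estimation and PSM filtering.
#
# Scores every distinct threshold by the decoy/target count ratio, converts
# to q-values, and retains target PSMs with q < 0.01 (the strict FDR < 0.01
# rule of the original analysis).

suppressMessages(library(itraqdep))

psms <- read_psm_tsv("results/sim/psms.tsv")
annotated <- compute_fdr(psms)
passed <- filter_fdr(annotated, threshold = 0.01)

write_psm_tsv(annotated, "results/sim/psms.annotated.tsv")
write_psm_tsv(passed, "results/sim/psms.passed.tsv")

cat(sprintf("%d of %d PSMs pass q < 0.01 (%d targets total, %d decoys rejected)\n",
            nrow(passed), nrow(psms), sum(!psms$is_decoy), sum(psms$is_decoy)))
cat(sprintf("score at the acceptance boundary: %.2f\n", min(passed$score)))
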