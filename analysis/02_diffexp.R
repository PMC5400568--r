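#!/usr/bin/env Rscript
# Step 2: differential expression, tumor vs normal.
#
# Reads the simulated matrix back through the validating readers, runs
# the per-probe Welch t-test on log2 intensities with linear fold
# changes, applies the fold change >= 2.0 / p < 0.05 screen, and writes
# the full DE table plus the filtered up/down lists.

library(ceRNAforge)

es <- read_expression("results/synthetic/matrix.tsv",
                      "results/synthetic/design.tsv",
                      "results/synthetic/annotation.tsv")
de <- run_diffexp(es)
flt <- filter_de(de, fc_min = 2.0, p_max = 0.05)

write.table(de, "results/diffexp_all.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(rbind(flt$up, flt$down), "results/diffexp_filtered.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

for (bt in c("lncRNA", "mRNA")) {
  cat(sprintf("%s: %d up, %d down (fc >= 2, p < 0.05)\n", bt,
              sum(flt$up$biotype == bt), sum(flt$down$biotype == bt)))
}
truth <- read.delim("results/synthetic/truth.tsv", comment.char = "#")
planted <- truth$probe_id[!is.na(truth$true_direction)]
hit <- intersect(c(flt$up$probe_id, flt$down$probe_id), planted)
cat(sprintf("planted DE probes recovered: %d / %d\n",
            length(hit), length(planted)))
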