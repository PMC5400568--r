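#!/usr/bin/env Rscript
# Step 1: generate the synthetic paired tumor/normal cohort.
#
# Emulates a 20-pair lncRNA+mRNA microarray study with five planted ceRNA
# triplets (shared tumor-elevated latent factor, fold change 4, pairwise
# r ~ 0.999), a miR-133b overexpression response table, transcript
# sequences carrying planted seed-match sites, and a 14-style Ct table.
# All files land under results/synthetic/ in the formats the pipeline
# readers consume, together with the machine-readable truth table.

library(ceRNAforge)

spec <- synthetic_spec(seed = 1)
cohort <- generate_cohort(spec)
write_cohort(cohort, "results/synthetic")

cat("cohort:", nrow(cohort$es$expr), "probes x", ncol(cohort$es$expr),
    "samples\n")
cat("planted triplets:", sum(cohort$truth$role == "triplet_lncRNA"), "\n")
cat("DE-only probes:", sum(cohort$truth$role == "de_only"), "\n")
cat("written to results/synthetic/\n")
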