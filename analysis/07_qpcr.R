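#!/usr/bin/env Rscript
# Step 7: qPCR validation statistics.
#
# Reads the simulated 2x20-sample Ct table (miR-133b vs U6; a planted
# target mRNA and its partner lncRNA vs GAPDH), computes 2^-DeltaCt
# relative expression, compares tumor vs normal with the paired
# two-tailed t-test on log2 expression, and correlates the
# target/partner pair.

library(ceRNAforge)

ct <- read_ct_table("results/synthetic/ct.tsv")
qs <- qpcr_summary(ct)
write.table(qs, "results/qpcr_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(qs, digits = 3)

other <- setdiff(unique(ct$target_name), "miR-133b")
a <- ct$expression[ct$target_name == other[1]]
b <- ct$expression[ct$target_name == other[2]]
cc <- expression_correlation(a, b)
cat(sprintf("correlation of %s and %s relative expression: r = %.3f, p = %.3g\n",
            other[1], other[2], cc$r, cc$p))
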