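#!/usr/bin/env Rscript
# Step 4: coding/non-coding co-expression screen.
#
# Correlates every candidate target mRNA with every lncRNA across all
# samples (log2 scale), attaches t-transform p-values, applies
# Benjamini-Hochberg over the full tested family, and keeps edges with
# |PCC| >= 0.995 and FDR < 0.05.

library(ceRNAforge)

es <- read_expression("results/synthetic/matrix.tsv",
                      "results/synthetic/design.tsv",
                      "results/synthetic/annotation.tsv")
cand <- read.delim("results/candidates.tsv")
lnc_ids <- es$annotation$probe_id[es$annotation$biotype == "lncRNA"]

edges <- build_cnc(es, cand$gene_symbol, lnc_ids,
                   pcc_min = 0.995, fdr_max = 0.05)
write.table(edges, "results/cnc_edges.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

all_pairs <- attr(edges, "all_pairs")
cat(sprintf("tested %d mRNA x %d lncRNA = %d pairs\n",
            nrow(cand), length(lnc_ids), nrow(all_pairs)))
cat(sprintf("retained %d edge(s) at |PCC| >= 0.995, FDR < 0.05:\n",
            nrow(edges)))
print(edges[, c("lncRNA_id", "mRNA_id", "r", "q", "sign")], digits = 4)
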