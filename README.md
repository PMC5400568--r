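# ceRNAforge

An R package for constructing miRNA-mediated lncRNA–mRNA **competing
endogenous RNA (ceRNA) networks** from paired tumor/normal expression
profiles combined with a miRNA-overexpression experiment. It was built
around the miR-133b / colorectal-cancer case: miR-133b is a
tumor-suppressor miRNA, and lncRNAs that carry miR-133b response
elements (MREs) and co-express tightly with miR-133b target genes are
candidate sponges that titrate the miRNA away from its targets.

The package is aimed at computational biologists who have (i) a
probes × samples expression matrix covering lncRNAs and mRNAs with a
paired tumor/normal design, (ii) a response table from a miRNA
overexpression experiment, and (iii) transcript sequences and/or
external MRE prediction tables, and who want a tested, seeded,
reproducible path from those inputs to a Cytoscape-ready network.

## The method

1. **Differential expression.** Per probe, linear fold change
   `FC = max(m_T/m_N, m_N/m_T)` with a direction label, a two-sided
   Welch *t*-test on log2 intensities, and Benjamini–Hochberg *q*
   values; the screen keeps `FC >= 2.0` and `p < 0.05`.
2. **Candidate targets.** Genes **down** on miRNA overexpression and
   **up** in tumor (both at the same thresholds) that possess an MRE.
3. **MRE evidence.** A canonical seed-match scanner (6mer, 7mer-A1,
   7mer-m8, 8mer; Watson–Crick only, transcript sense strand, 0-based
   half-open coordinates) plus ingestion of external predictor tables
   (RNA22/PITA style), combined by an intersection consensus rule.
4. **Co-expression (CNC) screen.** Pearson correlation of every
   candidate mRNA against every lncRNA across all samples; *p* from
   `t = r·sqrt(n−2)/sqrt(1−r²)`; BH over the full tested family; edges
   kept at `|PCC| >= 0.995`, `FDR < 0.05`.
5. **Assembly.** Triplets (lncRNA, miRNA, mRNA) where the lncRNA passed
   the DE screen, correlates with a candidate target, and carries a
   consensus MRE; exported as SIF/GraphML/TSV with typed nodes and
   edges (sequence-match, positive/negative correlation).
6. **GSEA.** From-scratch weighted Kolmogorov–Smirnov enrichment of
   gene sets over genes ranked by correlation with a lncRNA, with a
   sample-permutation null (ES, sign-normalized NES, nominal *p*,
   sign-stratified FDR); significance at `|NES| > 1`, `FDR < 0.2`.
   A hypergeometric over-representation test is included for DE lists.
7. **qPCR validation.** `2^-ΔCt` relative expression, paired two-tailed
   *t*-tests on log2 expression, and gene–gene correlations.

A seeded synthetic-data generator produces a full cohort (expression,
design, annotation, sequences with planted seed sites, perturbation
response, Ct tables) with a machine-readable truth table, so the whole
pipeline is testable end-to-end without any external download.

## Worked example

The package ships evidence tables for the miR-133b colorectal-cancer
case study (`inst/extdata/mir133b/`). Reconstructing the network:

```r
library(ceRNAforge)
wx <- mir133b_network()
wx$candidates$gene_symbol
#> [1] "CES1"   "EPAS1"  "GULP1"  "LTBP1"  "NR3C1"  "RHOA"   "TMEM71" "UBD"
length(wx$mre_lncrnas)
#> [1] 9
print(wx$network)
#> ceRNA network for miR-133b: 9 lncRNA node(s), 3 mRNA node(s), 21 edge(s)
sort(unique(wx$network$triplets$mRNA_id))
#> [1] "CES1"  "EPAS1" "UBD"
```

Eight candidate target genes survive the combined screen, nine lncRNAs
carry dual-predictor (RNA22 ∩ PITA) MRE support, and the assembled
network links them to three target mRNAs (UBD, EPAS1, CES1) around the
miR-133b hub — 12 sequence-match edges plus 9 signed correlation edges.

The `analysis/` directory holds the same flow as numbered drivers over
the synthetic cohort (`01_simulate.R` … `07_qpcr.R`), each writing its
tables under `results/`. On the default simulation they print, among
other things:

```
planted DE probes recovered: 30 / 30
retained 5 edge(s) at |PCC| >= 0.995, FDR < 0.05
planted triplets recovered exactly: TRUE
significant at |NES| > 1, FDR < 0.2: PLANTED_TARGETS
```

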