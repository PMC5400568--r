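---
title: "Methods: building a miRNA-mediated ceRNA network"
author: "ceRNAforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building a miRNA-mediated ceRNA network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAforge)
```

## The model

The competing-endogenous-RNA (ceRNA) hypothesis holds that transcripts
sharing miRNA response elements (MREs) compete for a limited miRNA
pool: a highly expressed lncRNA carrying MREs for a miRNA can sponge it
and de-repress the miRNA's mRNA targets. This package operationalizes
that idea for a single hub miRNA as a conjunction of observable
criteria over two expression experiments:

* the mRNA responds to the miRNA (down-regulated when the miRNA is
  overexpressed) and moves opposite to the miRNA in tumors (here: up,
  for a tumor-suppressor miRNA that is lost in tumors);
* the lncRNA is itself dysregulated in tumors and its expression tracks
  the candidate target across samples almost perfectly;
* both transcripts carry MREs for the miRNA.

Each retained (lncRNA, miRNA, mRNA) triplet is supported independently
by sequence evidence and by two layers of expression evidence. The
output is a tripartite network with one miRNA hub, sequence-match edges
from the hub to every RNA node, and signed correlation edges between
lncRNAs and mRNAs.

## Statistical components

**Differential expression.** Fold change is a linear-scale magnitude
`max(m_T/m_N, m_N/m_T)` with a direction label (ties labelled "up" so
output ordering is deterministic); the test is a two-sided Welch
*t*-test on log2 intensities. The screen thresholds the raw *p*
(`FC >= 2.0`, inclusive; `p < 0.05`, strict), matching the common
microarray reporting convention; BH *q* values are carried along for
reference. Welch rather than the pooled-variance test is the default
because group variances in tumor/normal designs are rarely equal; the
pooled test is available via `var_equal = TRUE`. The arrays are treated
as unpaired even though the design is patient-paired — this mirrors
the analysis convention the pipeline reproduces, and the paired
structure is still exploited by the qPCR stage.

**Co-expression.** Pearson correlation on log2 intensities across all
samples (tumor and normal jointly — the co-expression network is a
property of the full cohort), with *p* from the exact *t* transform
`t = r·sqrt(n-2)/sqrt(1-r^2)` on `n-2` df. Since an FDR is applied to
correlation screening, the BH family is the full set of tested
(candidate mRNA × lncRNA) pairs; this is the standard construction when
only the thresholds `|PCC| >= 0.995`, `FDR < 0.05` are prescribed. Both
edge signs are retained.

**Seed matching.** The built-in scanner reports the four canonical site
classes defined by Watson–Crick pairing with miRNA seed positions
2–7/2–8, with a required target-side A opposite position 1 for the A1
classes (regardless of the miRNA's first base, per the canonical
definition). G:U wobble, 3'-supplementary pairing and free-energy
scoring are deliberately out of scope: external predictors that model
those (RNA22-/PITA-style) are ingested as tables, and the consensus
rule — intersection over the configured predictor labels — decides MRE
status. Coordinates are 0-based half-open on the transcript sense
strand. Nested site classes are each reported, so an 8mer also yields
its 7mer/6mer sub-sites at consistent offsets.

**GSEA.** Genes are ranked by correlation with the lncRNA profile
(descending, ties broken alphabetically). The enrichment score is the
weighted Kolmogorov–Smirnov running-sum deviation (hit increments
`|r|^p` normalized over the set, `p = 1` by default; miss decrements
`1/(N-N_h)`); the maximum deviation from zero is taken, with a tie (to
numerical tolerance) resolved to the negative side, matching
established implementations. Because the phenotype is a continuous
lncRNA profile, "sample permutation" is implemented as permutation of
that profile across samples before re-ranking — the sample-level null
that preserves the gene–gene correlation structure. NES divides ES by
the mean magnitude of same-sign null scores; nominal *p* is the
same-sign null tail; FDR is the sign-stratified ratio of null to
observed NES tail fractions, clipped to [0, 1]. This is the published
construction of the reference method; bit-compatibility with its Java
implementation is not claimed (its FDR variant has known subtleties),
which is why the test suite cross-checks the ES against an independent
implementation and an exhaustive oracle rather than against archived
Java output. Degenerate sets (no overlap with the ranked list, or
covering it entirely) are skipped with a notice.

**qPCR.** Relative expression is `2^-ΔCt` with ΔCt = target Ct −
reference Ct (GAPDH for mRNA/lncRNA, U6 for the miRNA); technical
replicates are averaged on the Ct scale first. The tumor/normal
comparison is a two-tailed *t*-test on log2 relative expression,
*paired* by patient by default — for a matched tumor/non-tumor design
the paired reading is the defensible one — with the unpaired variant
behind a flag. All-zero paired differences give `p = 1` (no evidence of
a difference); constant non-zero differences are flagged degenerate
rather than assigned an artificial *p*.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `fc_min` | 2.0 | DE fold-change screen (linear, inclusive) |
| `p_max` | 0.05 | DE *p* screen (strict) |
| `pcc_min` | 0.995 | minimum absolute Pearson correlation |
| `cnc_fdr_max` | 0.05 | BH FDR ceiling for edges |
| `nes_min`, `gsea_fdr_max` | 1.0, 0.2 | GSEA significance |
| `n_perm` | 1000 | sample permutations |
| `min_site_class` | 7mer-A1 | weakest seed class counted as MRE |
| `predictors` | builtin | consensus labels (`c("RNA22","PITA")` for external tables) |

Defaults are the canonical thresholds of the screen the pipeline
reproduces; `pipeline_config()` validates ranges before any stage runs
and the run manifest always echoes the effective values.

## The synthetic cohort

`synthetic_spec()` defaults describe the emulated study: 20 patient
pairs, 500 lncRNA and 2000 mRNA probes, 5 planted ceRNA triplets with
fold change 4 and target correlation 0.999, plus 20 DE-only probes and
a log2-scale residual SD of 0.25 for null probes. Baseline log2
intensities are drawn per probe from N(8, 1.5) — a typical
microarray intensity range — and the shared latent factor of a planted
pair has SD 0.5 on top of the tumor shift. The residual SD of planted
probes is solved from the target correlation: with latent variance
`v = log2(FC)^2/4 + 0.5^2`, the residual variance is `v·(1/r − 1)`, so
the pair's theoretical correlation across the cohort equals `planted_r`
exactly. Transcripts are 500 nt — long enough to behave like real
transcript fragments under rejection sampling while keeping site
bookkeeping simple; null transcripts are rejection-sampled to contain
*no* canonical site for the configured miRNA (against the built-in
scanner only, keeping the truth self-contained), and planted
transcripts receive one 8mer insertion at a recorded position.

What the generator does **not** emulate: probe effects, batch and
hybridization artifacts, intensity-dependent variance, cross-hybridizing
probes, or realistic transcript base composition. Passing tests
therefore demonstrate that the pipeline's logic and statistics recover
exactly the structure the model class assumes — not that the thresholds
are optimal for any particular real microarray platform.

## Numerical and design choices

* The expression container carries a `scale_tag`; statistics that need
  log2 transform internally, so fold changes stay linear (as reported)
  while tests run on log2.
* Probes with any missing value are dropped with a warning; imputation
  is out of scope.
* Probes constant in both groups have an undefined *t*-test; they are
  flagged `NA` and excluded from the BH family rather than silently
  assigned `p = 1`.
* `|r| = 1` correlations get `p = 0` with a degeneracy flag rather than
  an error, since exact affine copies are legitimate planted cases.
* Gene symbols are harmonized by uppercasing on both sides; unmatched
  symbols simply fail the intersection (they cannot satisfy all
  criteria).
* The mRNA side's MRE requirement in assembly is inherited from the
  candidate set (whose selection already required it); the lncRNA side
  comes from the consensus rule. This mirrors the two-criteria flow of
  the screen the package reproduces.
* The worked-example fixtures use ENST00000366185 throughout for the
  CES1-linked lncRNA that one published table prints as
  ENST00000361155; the two identifiers appear to be a typographical
  inconsistency and the network counts are identical either way.
* Whether the original 8-gene screen applied its thresholds to both
  arrays is ambiguous in the source description; the package applies
  them to both (the stricter reading), configurable per call.

## Problem sizes used in validation

The test suite and acceptance script run the full pipeline on the
default 20-pair, 2500-probe cohort (20 seeded replicates for the
recovery rate), exhaustive enrichment-score enumeration on 10–12-gene
lists, 1000-instance oracle comparisons for each core statistic, and
200–1000-permutation GSEA runs. These sizes were chosen as the smallest
at which each property is sharply testable: planted-pair correlations
concentrate well above the 0.995 screen at n = 40 samples, and the
binomial/KS calibration checks have adequate power at a few thousand
null tests.

## Known limitations

* Single-hub networks only; multi-miRNA competition and ceRNA activity
  scores (e.g. conditional mutual information) are out of scope.
* The built-in scanner is presence/absence evidence; it does not rank
  sites and cannot reproduce external predictors' score cutoffs.
* GSEA FDR values are permutation-ratio estimates; at small `n_perm`
  they are coarse and can be exactly 0 for strongly enriched sets.
* The DE module offers no moderated (empirical-Bayes) statistics; for
  very small cohorts a limma-style analysis may be preferable upstream,
  with its output fed to the downstream stages.
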