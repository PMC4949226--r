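# cotarget

Tools for testing whether two transcription factors **co-occupy** and
**co-regulate** a shared set of target genes — the analysis pattern behind
studies of signaling crosstalk at the promoter level, such as the
convergence of the phytochrome (PIF) and ethylene (EIN3) pathways on shared
promoters in etiolated *Arabidopsis* seedlings. The package covers the full
chain from peak calls to regulatory-mode calls, plus a synthetic-data
generator with planted truth so every stage is testable without external
downloads.

## What it computes

* **Peak-to-gene assignment** — each ChIP peak, reduced to its summit (or
  midpoint), is assigned to genes through a strand-aware composite window:
  promoter (−5 kb to TSS), gene body (TSS–TES), downstream (TES + 1 kb);
  nearest-TSS or keep-all policies.
* **Target-class overlap** — decomposition into A-only / B-only / shared
  classes and the upper-tail hypergeometric test
  `P(X ≥ k)`, `X ~ Hypergeom(N, n_A, n_B)`, computed in log space so
  p-values far below double-precision underflow stay representable as
  log10 values, with fold enrichment `k / (n_A n_B / N)`.
* **Inter-peak proximity** — distances between the two factors'
  representative points on shared promoters, tested against a
  *random-target-promoter* permutation null that re-pairs each gene's
  factor-A peaks with another shared gene's factor-B peaks on TSS-relative
  offsets; empirical p = (1 + b)/(1 + m).
* **Metagene profile** — peak density over fixed-width promoter/downstream
  bins and a length-normalized gene body.
* **Expression integration** — multi-experiment merging with
  all/any-significant filters, ±2 log2 clamping, average-linkage
  clustering, exact-binomial sign concordance with explicit per-column
  sign conventions, and 2^−ΔΔCt / ChIP fold-enrichment helpers.
* **GSEA engine** — weighted Kolmogorov–Smirnov running sum
  (ES ∈ [−1, 1]), gene-set permutation null, NES, nominal p, and
  sign-stratified FDR q.
* **Regulatory-mode classifier** — Welch contrasts on log2 panels
  (WT / mutA / mutB / mutAB) label each gene `interdependent`
  (double mutant no lower than the singles), `additive` (double below both
  singles), `not_coactivated`, or `ambiguous`, with a residual-activity
  flag.
* **Synthetic studies** — `simulate_study()` writes a complete study
  (GFF3, narrowPeak, expression TSVs, genotype panels, GMT, truth JSON)
  with planted shared targets, proximity, concordance, and modes.

## Worked example

The `analysis/` directory is a numbered workflow over a simulated study
(2,000 genes; 500 and 130 targets, 60 shared; shared-promoter peak offsets
Normal(0, 50 bp)). Running it end to end:

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_target_classes.R
Rscript analysis/03_proximity.R
Rscript analysis/04_expression_integration.R
Rscript analysis/05_regulatory_modes.R
```

prints, among other things:

```
Target classes over 2000 genes
  A only : 440
  B only : 70
  shared : 60 (12.0% of A, 46.2% of B)
Overlap: 60 shared of 500 x 130 targets in a universe of 2000
  expected 32.50, fold enrichment 1.85, log10 p (upper) = -7.32
planted shared targets recovered exactly: TRUE

Proximity permutation test (median, 60 genes, 999 permutations)
  observed median = 39.000, null median = 1532.500, p = 0.001
fraction of shared promoters with peaks within 200 bp: 1.000

Sign concordance: 55 concordant / 5 discordant (of 60 genes), two-sided binomial p = 1.038e-11

confusion matrix (planted x called):
                 called
planted           additive interdependent not_coactivated
  additive              27              0               0
  interdependent         0             26               0
  not_coactivated        0              1               6
label recovery: 98.3% of 60 genes
```

Reading this: the assignment recovered the 60 planted shared targets
exactly; the 60-gene overlap is 1.85-fold over the 32.5 expected by chance
(log10 p −7.3); the two factors' peaks sit a median 39 bp apart on shared
promoters versus ~1.5 kb under the re-pairing null (p = 0.001, the
smallest value 999 permutations can produce); regulation direction agrees
between the two expression experiments for 55/60 significant shared
targets; and the genotype-panel classifier recovers 98% of the planted
regulatory modes. Per-gene and per-bin tables land under `results/`.

The same objects are available interactively:

```r
library(cotarget)
study <- simulate_study(seed = 1)
aa <- assign_peaks_to_genes(study$peaks_a, study$genes)
ab <- assign_peaks_to_genes(study$peaks_b, study$genes)
cl <- classify_targets(aa, ab, study$genes$gene_id)
hypergeometric_overlap(500, 130, length(cl$shared), 2000)
proximity_permutation_test(aa, ab, cl$shared, n_permutations = 999, seed = 1)
```

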