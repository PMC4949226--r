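#!/usr/bin/env Rscript

## Step 1 — simulate the study.
##
## Generates the complete synthetic study the rest of the workflow analyzes:
## a 2,000-gene annotation, ChIP peak sets for two factors with 60 planted
## shared targets (500 and 130 targets overall) whose shared-promoter peaks
## sit Normal(0, 50 bp) apart, two differential-expression experiments with
## 1.5 log2-unit effects and 90% sign concordance on the shared targets, and
## WT/single/single/double genotype panels with planted regulatory modes.
## Raw inputs land in scratch/sim/ (regenerable at will); the planted truth
## is serialized alongside them.

suppressPackageStartupMessages(library(cotarget))

outdir <- "scratch/sim"
study <- simulate_study(outdir = outdir, seed = 1L)

cat("Simulated study written to", outdir, "\n")
cat(sprintf("  genes          : %d on %d chromosomes\n",
            nrow(study$genes), length(unique(study$genes$chrom))))
cat(sprintf("  factor A peaks : %d\n", nrow(study$peaks_a)))
cat(sprintf("  factor B peaks : %d\n", nrow(study$peaks_b)))
cat(sprintf("  planted shared : %d genes\n", length(study$truth$shared)))
cat(sprintf("  expression     : %d experiments x %d genes\n",
            length(unique(study$expression$experiment_id)), nrow(study$genes)))
cat(sprintf("  genotype panels: %d genes x 4 genotypes x 3 replicates\n",
            length(study$truth$modes)))
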