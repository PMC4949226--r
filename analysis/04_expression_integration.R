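#!/usr/bin/env Rscript

## Step 4 — expression integration over the shared targets.
##
## Merges the two differential-expression experiments, filters at p < 0.05
## in both, clamps fold changes to +/- 2 for the clustered display, tests
## sign concordance between the experiments, clusters the significant genes
## by their expression pattern, and runs the gene set enrichment engine on
## experiment 1's ranking against the planted responsive set.

suppressPackageStartupMessages(library(cotarget))
dir.create("results", showWarnings = FALSE)

expr <- rbind(read_expression_table("scratch/sim/expr_exp1.tsv"),
              read_expression_table("scratch/sim/expr_exp2.tsv"))
sets <- read_gmt("scratch/sim/sets.gmt")
truth <- jsonlite::read_json("scratch/sim/truth.json", simplifyVector = TRUE)

fc <- merge_experiments(expr, alpha = 0.05, policy = "all_significant")
cat(sprintf("genes significant in both experiments: %d (planted responsive: %d)\n",
            nrow(fc$values), length(truth$shared)))
fc <- clamp_fold_changes(fc, 2.0)

conc <- sign_concordance(fc, "exp1", "exp2")
print(conc)

hc <- hierarchical_cluster(fc, metric = "euclidean")
ord <- rownames(fc$values)[hc$order]
cat(sprintf("clustered %d genes; first leaves: %s ...\n", length(ord),
            paste(head(ord, 5), collapse = ", ")))
clustered <- data.frame(gene_id = ord,
                        exp1 = fc$values[ord, "exp1"],
                        exp2 = fc$values[ord, "exp2"])
write.table(clustered, "results/clustered_fold_changes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

e1 <- expr[expr$experiment_id == "exp1", ]
ranked <- sort(setNames(e1$log2fc, e1$gene_id), decreasing = TRUE)
gene_sets <- list(
  planted_up = intersect(sets$planted_responsive, names(ranked)[ranked > 0]),
  planted_down = intersect(sets$planted_responsive, names(ranked)[ranked < 0]))
res <- gsea_significance(ranked, gene_sets, n_permutations = 1000L, seed = 1L)
cat("GSEA of the planted responsive set split by direction:\n")
print(res[, c("gene_set_id", "size", "es", "nes", "p_nominal", "fdr_q")],
      row.names = FALSE)

out <- res[, c("gene_set_id", "size", "es", "nes", "p_nominal", "fdr_q",
               "n_permutations", "seed")]
write.table(out, "results/gsea_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(
  list(n_significant_both = nrow(fc$values),
       n_concordant = conc$n_concordant, n_discordant = conc$n_discordant,
       binomial_p_two_sided = conc$binomial_p_two_sided),
  "results/concordance.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/clustered_fold_changes.tsv, results/gsea_results.tsv, results/concordance.json\n")
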