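## Synthetic study generator: genomes, peak sets, expression tables and
## genotype panels with planted, recorded truth. Defaults define the study
## conditions exercised by the analysis scripts and the acceptance checks.

#' Simulate a compact gene annotation
#'
#' Places non-overlapping genes with random strands along `n_chroms`
#' chromosomes. Gene lengths and intergenic gaps are uniform over the given
#' ranges. The default gap law keeps neighboring genes far enough apart that
#' a 5 kb promoter window never reaches past the midpoint to another gene's
#' TSS, so promoter peaks are unambiguous under nearest-TSS assignment.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_chroms Number of chromosomes.
#' @param gene_length_law `(min, max)` gene length in bp.
#' @param intergenic_law `(min, max)` gap between genes in bp.
#' @param seed RNG seed.
#' @return A gene-model table (see [gene_models()]).
#' @export
simulate_genome <- function(n_genes, n_chroms = 5L,
                            gene_length_law = c(1000L, 5000L),
                            intergenic_law = c(10500L, 18000L),
                            seed = 1L) {
  if (n_genes < 1L) stop_validation("n_genes must be >= 1")
  if (any(gene_length_law <= 0L) || gene_length_law[1L] > gene_length_law[2L]) {
    stop_validation("invalid gene_length_law")
  }
  if (any(intergenic_law <= 0L) || intergenic_law[1L] > intergenic_law[2L]) {
    stop_validation("invalid intergenic_law")
  }
  per_chrom <- (n_genes + n_chroms - 1L) %/% n_chroms
  if (per_chrom * (max(gene_length_law) + max(intergenic_law)) > 2^31 - 1) {
    stop_validation("infeasible spacing: chromosome length would overflow")
  }
  with_seed(seed, {
    lens <- sample(gene_length_law[1L]:gene_length_law[2L], n_genes, replace = TRUE)
    gaps <- sample(intergenic_law[1L]:intergenic_law[2L], n_genes, replace = TRUE)
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    chrom_of <- rep(sprintf("chr%d", seq_len(n_chroms)), length.out = n_genes,
                    each = per_chrom)[seq_len(n_genes)]
    start <- integer(n_genes)
    pos <- 0L
    cur <- chrom_of[1L]
    for (i in seq_len(n_genes)) {
      if (chrom_of[i] != cur) { pos <- 0L; cur <- chrom_of[i] }
      pos <- pos + gaps[i]
      start[i] <- pos
      pos <- pos + lens[i]
    }
    gene_models(sprintf("g%04d", seq_len(n_genes)), chrom_of, strands,
                start, start + lens)
  })
}

## Genomic position of a TSS-relative offset d on a gene row.
offset_to_genomic <- function(genes, idx, d) {
  ifelse(genes$strand[idx] == "+", genes$tss[idx] + d, genes$tss[idx] - d)
}

#' Simulate co-occupied peak sets with planted shared targets
#'
#' Draws target genes for two factors (a planted number of them shared),
#' places one fixed-width peak per target with its summit at a uniform
#' offset within the promoter window, and, on shared genes, couples factor
#' B's offset to factor A's with Normal(0, `sigma_shared_bp`) jitter
#' (truncated to the promoter window). `sigma_shared_bp = Inf` plants no
#' proximity: both factors draw offsets independently.
#'
#' @param genes Gene-model table.
#' @param n_targets_a,n_targets_b Target counts for the two factors.
#' @param n_shared Planted shared-target count.
#' @param sigma_shared_bp SD (bp) of the shared-promoter offset difference.
#' @param promoter_bp Promoter window used for the offset law (default 5000).
#' @param peak_width Peak interval width in bp (default 200, summit centered).
#' @param with_summits Emit summits (`TRUE`) or leave them absent so
#'   downstream code exercises the midpoint fallback.
#' @param seed RNG seed.
#' @return A list: `peaks_a`, `peaks_b` (peak sets) and `truth` (planted
#'   target sets, offsets, parameters, seed).
#' @export
simulate_cooccupancy <- function(genes, n_targets_a, n_targets_b, n_shared,
                                 sigma_shared_bp = 50, promoter_bp = 5000L,
                                 peak_width = 200L, with_summits = TRUE,
                                 seed = 1L) {
  n <- nrow(genes)
  if (n_shared > min(n_targets_a, n_targets_b) || max(n_targets_a, n_targets_b) > n) {
    stop_validation("need n_shared <= min(n_targets_a, n_targets_b) <= |genes|")
  }
  with_seed(seed, {
    ids <- sample.int(n, n_targets_a + n_targets_b - n_shared)
    shared_idx <- ids[seq_len(n_shared)]
    a_only_idx <- ids[n_shared + seq_len(n_targets_a - n_shared)]
    b_only_idx <- ids[n_targets_a + seq_len(n_targets_b - n_shared)]
    a_idx <- c(shared_idx, a_only_idx)
    b_idx <- c(shared_idx, b_only_idx)

    draw_offset <- function(m) as.integer(floor(runif(m, -promoter_bp, 0)))
    off_a <- draw_offset(length(a_idx))
    if (is.finite(sigma_shared_bp)) {
      jit <- round(rnorm(n_shared, 0, sigma_shared_bp))
      off_b_shared <- pmin(pmax(off_a[seq_len(n_shared)] + as.integer(jit),
                                -promoter_bp), -1L)
    } else {
      off_b_shared <- draw_offset(n_shared)
    }
    off_b <- c(off_b_shared, draw_offset(length(b_only_idx)))

    half <- peak_width %/% 2L
    mk <- function(idx, off, label) {
      pt <- as.integer(offset_to_genomic(genes, idx, off))
      ord <- order(genes$chrom[idx], pt)
      peak_set(genes$chrom[idx][ord], pmax(pt - half, 0L)[ord], (pt + half)[ord],
               peak_id = sprintf("%s_peak_%04d", label, seq_along(idx)),
               summit = if (with_summits) pt[ord] else NA,
               score = 100, factor_label = label)
    }
    truth <- list(
      shared = sort(genes$gene_id[shared_idx]),
      targets_a = sort(genes$gene_id[a_idx]),
      targets_b = sort(genes$gene_id[b_idx]),
      offsets_a = stats::setNames(off_a, genes$gene_id[a_idx]),
      offsets_b = stats::setNames(off_b, genes$gene_id[b_idx]),
      sigma_shared_bp = sigma_shared_bp,
      promoter_bp = as.integer(promoter_bp),
      peak_width = as.integer(peak_width),
      seed = as.integer(seed)
    )
    list(peaks_a = mk(a_idx, off_a, "factorA"),
         peaks_b = mk(b_idx, off_b, "factorB"),
         truth = truth)
  })
}

#' Simulate differential-expression tables over planted targets
#'
#' Shared targets receive a log2 fold change of `± effect_log2` plus
#' Normal(0, `noise_sd`) noise; the sign agrees across experiments with
#' probability `concordance_prob` (relative to the first experiment's sign).
#' Non-targets receive pure noise. P-values are two-sided z-tests of each
#' value against the noise law, so under `effect_log2 = 0` they are uniform.
#'
#' @param genes Gene-model table (the expression universe).
#' @param shared Character vector of planted responsive gene ids.
#' @param n_experiments Number of experiments.
#' @param effect_log2 Planted |log2 fold change| (default 1.5).
#' @param concordance_prob Cross-experiment sign agreement (default 0.9).
#' @param noise_sd Noise SD in log2 units (default 0.3).
#' @param seed RNG seed.
#' @return Long `data.frame` of expression records; attribute `truth` holds
#'   the planted signs per experiment.
#' @export
simulate_expression <- function(genes, shared, n_experiments = 2L,
                                effect_log2 = 1.5, concordance_prob = 0.9,
                                noise_sd = 0.3, seed = 1L) {
  if (concordance_prob < 0 || concordance_prob > 1) {
    stop_validation("concordance_prob must be in [0,1]")
  }
  if (noise_sd <= 0) stop_validation("noise_sd must be > 0")
  with_seed(seed, {
    ids <- genes$gene_id
    is_shared <- ids %in% shared
    base_sign <- ifelse(runif(sum(is_shared)) < 0.5, -1, 1)
    recs <- lapply(seq_len(n_experiments), function(e) {
      sgn <- if (e == 1L) base_sign else {
        ifelse(runif(length(base_sign)) < concordance_prob, base_sign, -base_sign)
      }
      mu <- numeric(length(ids))
      mu[is_shared] <- sgn * effect_log2
      v <- mu + rnorm(length(ids), 0, noise_sd)
      data.frame(gene_id = ids, log2fc = v,
                 p_value = 2 * stats::pnorm(-abs(v) / noise_sd),
                 experiment_id = sprintf("exp%d", e), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, recs)
    attr(out, "truth") <- list(shared = sort(shared), effect_log2 = effect_log2,
                               concordance_prob = concordance_prob,
                               noise_sd = noise_sd, seed = as.integer(seed))
    out
  })
}

#' Simulate genotype expression panels with planted regulatory modes
#'
#' WT expression is 1. Interdependent genes drop both single mutants and the
#' double to `2^-single_drop`; additive genes drop the double a further
#' `double_extra_drop` log2 units; `not_coactivated` genes stay at WT level.
#' Replicates carry multiplicative lognormal noise at coefficient of
#' variation `cv`.
#'
#' @param gene_modes Named character vector: planted label per gene
#'   (`interdependent`, `additive`, `not_coactivated`).
#' @param single_drop,double_extra_drop Planted effects in log2 units
#'   (defaults 1.5 and 1.0).
#' @param n_replicates Replicates per genotype (default 3).
#' @param cv Replicate coefficient of variation (default 0.1).
#' @param seed RNG seed.
#' @return Long panel `data.frame` (`gene_id`, `genotype`, `replicate`,
#'   `value`); attribute `truth` records the planted modes and parameters.
#' @export
simulate_genotype_panels <- function(gene_modes, single_drop = 1.5,
                                     double_extra_drop = 1.0,
                                     n_replicates = 3L, cv = 0.1, seed = 1L) {
  if (n_replicates < 2L) stop_validation("n_replicates must be >= 2")
  labs <- c("interdependent", "additive", "not_coactivated")
  if (!all(gene_modes %in% labs)) {
    stop_validation("gene_modes labels must be in: ", paste(labs, collapse = ", "))
  }
  sdlog <- sqrt(log(1 + cv^2))
  with_seed(seed, {
    rows <- lapply(names(gene_modes), function(g) {
      mode <- gene_modes[[g]]
      mu <- switch(mode,
        not_coactivated = c(WT = 1, mutA = 1, mutB = 1, mutAB = 1),
        interdependent = c(WT = 1, mutA = 2^-single_drop, mutB = 2^-single_drop,
                           mutAB = 2^-single_drop),
        additive = c(WT = 1, mutA = 2^-single_drop, mutB = 2^-single_drop,
                     mutAB = 2^-(single_drop + double_extra_drop)))
      noise <- if (cv > 0) {
        stats::rlnorm(4L * n_replicates, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      } else rep(1, 4L * n_replicates)
      data.frame(gene_id = g,
                 genotype = rep(names(mu), each = n_replicates),
                 replicate = rep(seq_len(n_replicates), times = 4L),
                 value = rep(mu, each = n_replicates) * noise,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(modes = gene_modes, single_drop = single_drop,
                               double_extra_drop = double_extra_drop,
                               n_replicates = as.integer(n_replicates),
                               cv = cv, seed = as.integer(seed))
    out
  })
}

#' Simulate a full co-occupancy study and write it to disk
#'
#' Fans one master seed out to independent child seeds (see [split_seed()])
#' for the genome, the peak sets, the expression tables and the genotype
#' panels, writes every input format the pipeline reads (GFF3 annotation,
#' narrowPeak per factor, expression TSVs, panel TSV, a GMT of the planted
#' responsive set) plus `truth.json`, and returns everything in memory.
#'
#' @param outdir Output directory (created if needed); `NULL` skips writing.
#' @param n_genes,n_targets_a,n_targets_b,n_shared Study dimensions
#'   (defaults 2000, 500, 130, 60).
#' @param sigma_shared_bp Planted shared-promoter proximity SD (default 50).
#' @param n_experiments,effect_log2,concordance_prob,noise_sd Expression
#'   parameters.
#' @param mode_fractions Named fractions of shared genes per planted mode.
#' @param seed Master seed.
#' @return A list: `genes`, `peaks_a`, `peaks_b`, `expression`, `panels`,
#'   `gene_sets`, `truth`.
#' @export
simulate_study <- function(outdir = NULL, n_genes = 2000L, n_targets_a = 500L,
                           n_targets_b = 130L, n_shared = 60L,
                           sigma_shared_bp = 50, n_experiments = 2L,
                           effect_log2 = 1.5, concordance_prob = 0.9,
                           noise_sd = 0.3,
                           mode_fractions = c(interdependent = 0.4,
                                              additive = 0.4,
                                              not_coactivated = 0.2),
                           seed = 1L) {
  child <- split_seed(seed, 5L)
  genes <- simulate_genome(n_genes, seed = child[1L])
  occ <- simulate_cooccupancy(genes, n_targets_a, n_targets_b, n_shared,
                              sigma_shared_bp = sigma_shared_bp,
                              seed = child[2L])
  expr <- simulate_expression(genes, occ$truth$shared,
                              n_experiments = n_experiments,
                              effect_log2 = effect_log2,
                              concordance_prob = concordance_prob,
                              noise_sd = noise_sd, seed = child[3L])
  shared <- occ$truth$shared
  modes <- with_seed(child[4L], {
    stats::setNames(sample(names(mode_fractions), length(shared), replace = TRUE,
                           prob = mode_fractions), shared)
  })
  panels <- simulate_genotype_panels(modes, seed = child[5L])
  gene_sets <- list(planted_responsive = shared)
  truth <- c(occ$truth,
             list(modes = as.list(modes),
                  expression = attr(expr, "truth")[-1L],
                  master_seed = as.integer(seed),
                  child_seeds = as.integer(child)))
  out <- list(genes = genes, peaks_a = occ$peaks_a, peaks_b = occ$peaks_b,
              expression = expr, panels = panels, gene_sets = gene_sets,
              truth = truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_gene_models(genes, file.path(outdir, "genes.gff3"), "gff3")
    write_peaks(occ$peaks_a, file.path(outdir, "factorA.narrowPeak"))
    write_peaks(occ$peaks_b, file.path(outdir, "factorB.narrowPeak"))
    for (e in unique(expr$experiment_id)) {
      write_expression_table(expr[expr$experiment_id == e, ],
                             file.path(outdir, sprintf("expr_%s.tsv", e)))
    }
    write_genotype_panels(panels, file.path(outdir, "panels.tsv"))
    write_gmt(gene_sets, file.path(outdir, "sets.gmt"))
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
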