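#' Upper-tail hypergeometric test for target-set overlap
#'
#' Tests whether two factors share more target genes than expected by chance
#' when drawing target sets of the observed sizes from a common universe.
#' Computes `P(X >= n_shared)` for `X ~ Hypergeometric(universe_size, n_a,
#' n_b)` in log space, so overlaps with p far below the smallest
#' representable double are reported as finite `log10` values.
#'
#' @param n_a,n_b Target-set sizes of the two factors.
#' @param n_shared Observed overlap.
#' @param universe_size Number of genes in the common universe.
#' @return A list of class `overlap_stat`: `n_a`, `n_b`, `n_shared`,
#'   `universe_size`, `log10_p_upper`, `p_upper` (0 when underflowed),
#'   `expected`, `fold_enrichment`.
#' @export
hypergeometric_overlap <- function(n_a, n_b, n_shared, universe_size) {
  if (any(c(n_a, n_b, n_shared, universe_size) < 0)) {
    stop_validation("counts must be non-negative")
  }
  if (n_shared > min(n_a, n_b)) stop_validation("n_shared exceeds min(n_a, n_b)")
  if (max(n_a, n_b) > universe_size) stop_validation("set larger than universe")
  if (n_shared < n_a + n_b - universe_size) {
    stop_validation("impossible configuration: overlap below forced minimum")
  }
  ## P(X >= k) = P(X > k - 1); phyper works on log-gamma internally.
  log_p <- stats::phyper(n_shared - 1, n_a, universe_size - n_a, n_b,
                         lower.tail = FALSE, log.p = TRUE)
  expected <- n_a * n_b / universe_size
  out <- list(n_a = n_a, n_b = n_b, n_shared = n_shared,
              universe_size = universe_size,
              log10_p_upper = log_p / log(10),
              p_upper = exp(log_p),
              expected = expected,
              fold_enrichment = if (expected > 0) n_shared / expected else NA_real_)
  class(out) <- "overlap_stat"
  out
}

#' @export
print.overlap_stat <- function(x, ...) {
  cat(sprintf("Overlap: %d shared of %d x %d targets in a universe of %d\n",
              x$n_shared, x$n_a, x$n_b, x$universe_size))
  cat(sprintf("  expected %.2f, fold enrichment %.2f, log10 p (upper) = %.2f\n",
              x$expected, x$fold_enrichment, x$log10_p_upper))
  invisible(x)
}

## TSS-relative offsets per gene for one factor, restricted to `shared`.
offsets_by_gene <- function(assignment, shared) {
  sub <- assignment[assignment$gene_id %in% shared, , drop = FALSE]
  split(sub[, c("peak_id", "offset")], factor(sub$gene_id, levels = sort(shared)))
}

#' Inter-peak distances on shared target genes
#'
#' Distances between the two factors' representative points on each shared
#' gene, computed from TSS-relative offsets (equivalently, genomic distance,
#' since both offsets share the gene's orientation).
#'
#' @param assign_a,assign_b Assignments ([assign_peaks_to_genes()]).
#' @param shared Character vector of shared target gene ids.
#' @param pairing `"nearest"` keeps one pair per gene (the cross-factor pair
#'   at minimal distance); `"all_pairs"` keeps every cross-factor pair.
#' @return A `data.frame`: `gene_id`, `peak_id_a`, `peak_id_b`, `distance`.
#' @export
interpeak_distances <- function(assign_a, assign_b, shared,
                                pairing = c("nearest", "all_pairs")) {
  pairing <- match.arg(pairing)
  offs_a <- offsets_by_gene(assign_a, shared)
  offs_b <- offsets_by_gene(assign_b, shared)
  lacking <- names(offs_a)[vapply(offs_a, nrow, 0L) == 0L |
                           vapply(offs_b, nrow, 0L) == 0L]
  if (length(lacking)) {
    stop_validation("shared gene(s) lacking a peak from one factor: ",
                    paste(utils::head(lacking, 5L), collapse = ", "))
  }
  res <- lapply(names(offs_a), function(g) {
    a <- offs_a[[g]]; b <- offs_b[[g]]
    grid <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    d <- abs(a$offset[grid$i] - b$offset[grid$j])
    if (pairing == "nearest") {
      k <- which.min(d)
      grid <- grid[k, , drop = FALSE]; d <- d[k]
    }
    data.frame(gene_id = g, peak_id_a = a$peak_id[grid$i],
               peak_id_b = b$peak_id[grid$j], distance = as.integer(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fraction of peak pairs within a distance threshold
#' @param pairs Output of [interpeak_distances()].
#' @param threshold_bp Distance threshold in bp.
#' @return Fraction of pairs with `distance <= threshold_bp`.
#' @export
fraction_within <- function(pairs, threshold_bp) {
  if (is.null(pairs) || nrow(pairs) == 0L) stop_validation("no distance pairs")
  mean(pairs$distance <= threshold_bp)
}

## Null statistic machinery: re-pair gene i's factor-A offsets with the
## factor-B offsets of a uniformly drawn *different* shared gene. Offsets are
## TSS-relative so cross-gene distances remain comparable.
null_repairing <- function(n) {
  j <- sample.int(n - 1L, n, replace = TRUE)
  ifelse(j >= seq_len(n), j + 1L, j)          # uniform over the other n-1 genes
}

null_statistic <- function(a_list, b_list, stat_fun, a_vec = NULL, b_vec = NULL) {
  n <- length(a_list)
  j <- null_repairing(n)
  d <- if (!is.null(a_vec)) {
    abs(a_vec - b_vec[j])                     # one peak per factor per gene
  } else {
    vapply(seq_len(n), function(i) {
      min(abs(outer(a_list[[i]], b_list[[j[i]]], "-")))
    }, 0)
  }
  stat_fun(d)
}

#' Permutation test for inter-peak proximity on shared promoters
#'
#' Tests whether the two factors bind closer together on their shared target
#' genes than expected if each factor's positional preferences were
#' independent. The null re-pairs each shared gene's factor-A peaks with the
#' factor-B peaks of a different, uniformly drawn shared gene (self-pairing
#' excluded; a derangement is not enforced), recomputes nearest cross-factor
#' distances on TSS-relative offsets, and records the chosen statistic. The
#' empirical p-value uses the `(1 + b) / (1 + m)` estimator: lower tail for
#' the median (closer than chance), upper tail for `fraction_within`.
#'
#' @param assign_a,assign_b Assignments ([assign_peaks_to_genes()]).
#' @param shared Shared target gene ids (at least 5).
#' @param statistic `"median"` or `"fraction_within"`.
#' @param threshold_bp Threshold for `fraction_within` (default 200).
#' @param n_permutations Number of null draws (default 999).
#' @param seed RNG seed.
#' @return A list of class `proximity_result`: `observed` (distance pairs),
#'   `statistic_name`, `observed_statistic`, `null_statistics`,
#'   `p_empirical`, `n_permutations`, `threshold_bp`, `seed`.
#' @export
proximity_permutation_test <- function(assign_a, assign_b, shared,
                                       statistic = c("median", "fraction_within"),
                                       threshold_bp = 200L,
                                       n_permutations = 999L, seed = 1L) {
  statistic <- match.arg(statistic)
  if (length(shared) < 5L) {
    stop_validation("need at least 5 shared genes for the permutation null")
  }
  if (n_permutations < 1L) stop_usage("n_permutations must be >= 1")

  observed <- interpeak_distances(assign_a, assign_b, shared, pairing = "nearest")
  stat_fun <- if (statistic == "median") {
    function(d) stats::median(d)
  } else {
    function(d) mean(d <= threshold_bp)
  }
  obs_stat <- stat_fun(observed$distance)

  a_list <- lapply(offsets_by_gene(assign_a, shared), function(x) x$offset)
  b_list <- lapply(offsets_by_gene(assign_b, shared), function(x) x$offset)
  single <- all(lengths(a_list) == 1L) && all(lengths(b_list) == 1L)
  a_vec <- if (single) unlist(a_list) else NULL
  b_vec <- if (single) unlist(b_list) else NULL
  nulls <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(k) {
      null_statistic(a_list, b_list, stat_fun, a_vec, b_vec)
    }, 0)
  })

  b <- if (statistic == "median") sum(nulls <= obs_stat) else sum(nulls >= obs_stat)
  out <- list(observed = observed, statistic_name = statistic,
              observed_statistic = obs_stat, null_statistics = nulls,
              p_empirical = (1 + b) / (n_permutations + 1),
              n_permutations = as.integer(n_permutations),
              threshold_bp = as.integer(threshold_bp), seed = as.integer(seed))
  class(out) <- "proximity_result"
  out
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("Proximity permutation test (%s, %d genes, %d permutations)\n",
              x$statistic_name, nrow(x$observed), x$n_permutations))
  cat(sprintf("  observed %s = %.3f, null median = %.3f, p = %.4g\n",
              x$statistic_name, x$observed_statistic,
              stats::median(x$null_statistics), x$p_empirical))
  invisible(x)
}

#' Metagene profile of peak positions
#'
#' Bins assigned peak positions along a composite metagene: fixed-width bins
#' over the promoter (`promoter_bp` upstream of the TSS) and the downstream
#' region (`downstream_bp` past the TES), and length-normalized bins over the
#' gene body (position rescaled to `[0, 1)` by `(point - TSS) / (TES - TSS)`,
#' strand-aware).
#'
#' @param assignments A single assignment or a named list of assignments
#'   (one per factor).
#' @param genes Gene-model table used for body lengths.
#' @param promoter_bp,downstream_bp Window extents (must match the
#'   assignment's windows).
#' @param n_promoter_bins,n_body_bins,n_downstream_bins Bin counts.
#' @return A list of class `metagene_profile` with the layout, a
#'   `counts` matrix (factor x bin) and a `density` matrix (rows sum to 1),
#'   plus `n_skipped` zero-length genes.
#' @export
metagene_profile <- function(assignments, genes, promoter_bp = 5000L,
                             downstream_bp = 1000L, n_promoter_bins = 25L,
                             n_body_bins = 20L, n_downstream_bins = 5L) {
  if (is.data.frame(assignments)) {
    lbl <- attr(assignments, "factor_label")
    assignments <- stats::setNames(list(assignments),
                                   if (is.null(lbl)) "factor" else lbl)
  }
  if (any(c(n_promoter_bins, n_body_bins, n_downstream_bins) < 1L)) {
    stop_usage("bin counts must be >= 1")
  }
  L <- abs(genes$tes - genes$tss)
  names(L) <- genes$gene_id
  n_bins <- n_promoter_bins + n_body_bins + n_downstream_bins
  counts <- matrix(0L, nrow = length(assignments), ncol = n_bins,
                   dimnames = list(names(assignments), NULL))
  n_skipped <- 0L
  for (f in seq_along(assignments)) {
    a <- assignments[[f]]
    len <- L[a$gene_id]
    zero <- len == 0L
    if (any(zero)) {
      n_skipped <- n_skipped + sum(zero)
      a <- a[!zero, , drop = FALSE]
      len <- len[!zero]
    }
    d <- a$offset
    bin <- integer(nrow(a))
    pro <- d < 0L
    bin[pro] <- pmin(floor((d[pro] + promoter_bp) / (promoter_bp / n_promoter_bins)),
                     n_promoter_bins - 1L)
    body <- d >= 0L & d < len
    bin[body] <- n_promoter_bins +
      pmin(floor(d[body] / len[body] * n_body_bins), n_body_bins - 1L)
    down <- d >= len
    bin[down] <- n_promoter_bins + n_body_bins +
      pmin(floor((d[down] - len[down]) / (downstream_bp / n_downstream_bins)),
           n_downstream_bins - 1L)
    tab <- tabulate(bin + 1L, nbins = n_bins)
    counts[f, ] <- tab
  }
  if (n_skipped > 0L) {
    warning(sprintf("skipped %d assignment(s) on zero-length genes", n_skipped))
  }
  totals <- rowSums(counts)
  density <- counts / ifelse(totals > 0, totals, 1)
  out <- list(promoter_bp = as.integer(promoter_bp),
              downstream_bp = as.integer(downstream_bp),
              n_promoter_bins = as.integer(n_promoter_bins),
              n_body_bins = as.integer(n_body_bins),
              n_downstream_bins = as.integer(n_downstream_bins),
              counts = counts, density = density, n_skipped = n_skipped)
  class(out) <- "metagene_profile"
  out
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("Metagene profile: %d promoter + %d body + %d downstream bins\n",
              x$n_promoter_bins, x$n_body_bins, x$n_downstream_bins))
  for (f in rownames(x$counts)) {
    cat(sprintf("  %s: %d peaks\n", f, sum(x$counts[f, ])))
  }
  invisible(x)
}
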