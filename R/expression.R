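#' Merge differential-expression experiments into a fold-change matrix
#'
#' Combines per-experiment records into gene x experiment matrices of log2
#' fold changes and p-values, retaining genes by a significance policy:
#' `all_significant` keeps genes with `p < alpha` in every experiment (genes
#' absent from any experiment are dropped); `any_significant` keeps genes
#' with `p < alpha` in at least one experiment (missing entries are `NA`).
#'
#' @param records Long `data.frame` of expression records
#'   (`gene_id`, `log2fc`, `p_value`, `experiment_id`), e.g. rbind-ed
#'   outputs of [read_expression_table()].
#' @param alpha Significance threshold (default 0.05).
#' @param policy `"all_significant"` or `"any_significant"`.
#' @return A list of class `fc_matrix`: `values` and `pvalues` matrices
#'   (genes x experiments), `clamp_limit` (`NA` until clamped).
#' @export
merge_experiments <- function(records, alpha = 0.05,
                              policy = c("all_significant", "any_significant")) {
  policy <- match.arg(policy)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_usage("alpha must be in (0, 1)")
  }
  exps <- unique(records$experiment_id)
  if (length(exps) < 1L) stop_validation("no experiments in input")
  genes <- sort(unique(records$gene_id))
  values <- matrix(NA_real_, length(genes), length(exps),
                   dimnames = list(genes, exps))
  pvalues <- values
  for (e in exps) {
    sub <- records[records$experiment_id == e, , drop = FALSE]
    if (anyDuplicated(sub$gene_id)) {
      stop_validation("duplicate gene_id within experiment ", e)
    }
    values[sub$gene_id, e] <- sub$log2fc
    pvalues[sub$gene_id, e] <- sub$p_value
  }
  sig <- !is.na(pvalues) & pvalues < alpha
  keep <- if (policy == "all_significant") {
    rowSums(sig) == length(exps)            # NA p counts as not significant
  } else {
    rowSums(sig) >= 1L
  }
  out <- list(values = values[keep, , drop = FALSE],
              pvalues = pvalues[keep, , drop = FALSE],
              clamp_limit = NA_real_)
  class(out) <- "fc_matrix"
  out
}

#' Clamp log2 fold changes to a symmetric limit
#'
#' Rescales extreme values into `[-limit, +limit]` for display-oriented
#' clustering; idempotent and order-preserving.
#'
#' @param fc A `fc_matrix` from [merge_experiments()].
#' @param limit Positive clamp limit (default 2.0 log2 units).
#' @return The clamped `fc_matrix` with `clamp_limit` recorded.
#' @export
clamp_fold_changes <- function(fc, limit = 2.0) {
  if (!is.numeric(limit) || limit <= 0) stop_usage("limit must be > 0")
  fc$values <- pmin(pmax(fc$values, -limit), limit)
  fc$clamp_limit <- limit
  fc
}

#' Sign concordance between two experiments
#'
#' Compares per-gene regulation direction between two experiment columns
#' after applying an explicit sign convention per column (so that e.g. a
#' loss-of-function contrast can be flipped and "inverse correlation" maps
#' to concordant regulation). Genes with a zero or missing value in either
#' column are excluded. An exact two-sided binomial test compares the
#' concordant count against 0.5.
#'
#' @param fc A `fc_matrix`.
#' @param col_x,col_y Experiment ids of the two columns.
#' @param sign_convention Numeric length-2 vector of `+1`/`-1` multipliers
#'   applied to `col_x` and `col_y` before comparison.
#' @return A list of class `concordance_result`: `n_total`, `n_concordant`,
#'   `n_discordant`, `binomial_p_two_sided`.
#' @export
sign_concordance <- function(fc, col_x, col_y, sign_convention = c(1, 1)) {
  if (!all(c(col_x, col_y) %in% colnames(fc$values))) {
    stop_validation("experiment column not present")
  }
  if (!all(sign_convention %in% c(-1, 1)) || length(sign_convention) != 2L) {
    stop_usage("sign_convention must be two values in {-1, +1}")
  }
  x <- fc$values[, col_x] * sign_convention[1L]
  y <- fc$values[, col_y] * sign_convention[2L]
  ok <- !is.na(x) & !is.na(y) & x != 0 & y != 0
  if (!any(ok)) stop_validation("no genes with nonzero values in both columns")
  conc <- sign(x[ok]) == sign(y[ok])
  n_eff <- sum(ok)
  out <- list(n_total = nrow(fc$values),
              n_concordant = sum(conc),
              n_discordant = n_eff - sum(conc),
              binomial_p_two_sided =
                stats::binom.test(sum(conc), n_eff, p = 0.5,
                                  alternative = "two.sided")$p.value)
  class(out) <- "concordance_result"
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Sign concordance: %d concordant / %d discordant (of %d genes), two-sided binomial p = %.4g\n",
              x$n_concordant, x$n_discordant, x$n_total, x$binomial_p_two_sided))
  invisible(x)
}

#' Average-linkage hierarchical clustering of genes
#'
#' Agglomerative clustering of the fold-change matrix rows, with either
#' Euclidean distance or correlation distance (`1 - Pearson r`).
#'
#' @param fc A `fc_matrix` with at least two rows.
#' @param metric `"one_minus_pearson"` or `"euclidean"`.
#' @return An object of class `hclust` (merge heights are non-decreasing for
#'   average linkage on a metric input); leaf order in `$order`.
#' @export
hierarchical_cluster <- function(fc, metric = c("one_minus_pearson", "euclidean")) {
  metric <- match.arg(metric)
  m <- fc$values
  if (nrow(m) < 2L) stop_validation("need at least 2 genes to cluster")
  if (metric == "one_minus_pearson") {
    v <- apply(m, 1L, stats::sd)
    if (any(is.na(v) | v == 0)) {
      stop_validation("constant row(s) under correlation metric: ",
                      paste(utils::head(rownames(m)[is.na(v) | v == 0], 5L),
                            collapse = ", "))
    }
    d <- stats::as.dist(1 - stats::cor(t(m)))
  } else {
    d <- stats::dist(m, method = "euclidean")
  }
  stats::hclust(d, method = "average")
}

#' Relative expression by the 2^-ddCt convention
#'
#' Standard Livak quantification for qPCR: the target gene's Ct is
#' normalized to a reference gene (e.g. PP2A) within each sample, then to a
#' calibrator sample.
#'
#' @param ct_target,ct_reference Ct values in the sample of interest.
#' @param ct_target_cal,ct_reference_cal Ct values in the calibrator sample.
#' @return `2^-ddCt`, the expression relative to the calibrator.
#' @export
relative_expression <- function(ct_target, ct_reference, ct_target_cal,
                                ct_reference_cal) {
  stopifnot(is.finite(ct_target), is.finite(ct_reference),
            is.finite(ct_target_cal), is.finite(ct_reference_cal))
  ddct <- (ct_target - ct_reference) - (ct_target_cal - ct_reference_cal)
  2^(-ddct)
}

#' ChIP-qPCR fold enrichment
#'
#' Enrichment of a target region in the IP over input, normalized to a
#' non-bound control region measured in the same samples.
#'
#' @param ct_ip_target,ct_input_target Ct of the target region in IP / input.
#' @param ct_ip_control,ct_input_control Ct of the control region in IP / input.
#' @return Fold enrichment relative to the control region.
#' @export
chip_fold_enrichment <- function(ct_ip_target, ct_input_target,
                                 ct_ip_control, ct_input_control) {
  stopifnot(is.finite(ct_ip_target), is.finite(ct_input_target),
            is.finite(ct_ip_control), is.finite(ct_input_control))
  2^(-(ct_ip_target - ct_input_target)) / 2^(-(ct_ip_control - ct_input_control))
}
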