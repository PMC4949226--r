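#' Assign ChIP peaks to genes by promoter/body/downstream windows
#'
#' Each peak is reduced to its representative point (summit, else midpoint)
#' and assigned to a gene when that point falls inside the gene's composite
#' strand-aware window: `promoter_bp` upstream of the TSS through
#' `downstream_bp` past the TES. In TSS-relative offset coordinates the
#' sub-windows are `[-promoter_bp, 0)` (promoter), `[0, L)` (gene body,
#' `L = |TES - TSS|`), and `[L, L + downstream_bp)` (3'), half-open on each
#' downstream edge.
#'
#' @param peaks A peak set ([peak_set()] / [read_peaks()]).
#' @param genes Gene-model table ([gene_models()]).
#' @param promoter_bp Upstream extent of the promoter window (default 5000).
#' @param downstream_bp Extent past the TES (default 1000).
#' @param policy `"nearest_tss"` (a peak inside several windows goes to the
#'   gene with smallest `|offset|`, ties broken by lexicographic `gene_id`)
#'   or `"all"` (every containing gene).
#' @return A `data.frame` with columns `gene_id`, `peak_id`, `region`
#'   (`promoter`/`body`/`three_prime`), `offset` (signed bp from TSS,
#'   strand-aware), plus attributes `factor_label` and `n_skipped`
#'   (peaks on chromosomes absent from the annotation).
#' @export
assign_peaks_to_genes <- function(peaks, genes, promoter_bp = 5000L,
                                  downstream_bp = 1000L,
                                  policy = c("nearest_tss", "all")) {
  policy <- match.arg(policy)
  if (nrow(genes) == 0L) stop_validation("empty gene collection")
  promoter_bp <- as.integer(promoter_bp)
  downstream_bp <- as.integer(downstream_bp)

  pts <- peak_points(peaks)
  known <- peaks$chrom %in% unique(genes$chrom)
  n_skipped <- sum(!known)
  if (n_skipped > 0L) {
    warning(sprintf("skipping %d peak(s) on chromosomes absent from the annotation",
                    n_skipped))
  }

  empty <- data.frame(gene_id = character(0), peak_id = character(0),
                      region = character(0), offset = integer(0),
                      stringsAsFactors = FALSE)
  if (!any(known)) {
    attr(empty, "factor_label") <- attr(peaks, "factor_label")
    attr(empty, "n_skipped") <- n_skipped
    return(empty)
  }

  L <- abs(genes$tes - genes$tss)
  ## Generous candidate windows (exact filtering below is in offset space).
  pad <- promoter_bp + downstream_bp
  win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(genes$start + 1L - pad, 1L),
                     end = genes$end + pad)
  )
  qry <- GenomicRanges::GRanges(peaks$chrom[known],
                                IRanges::IRanges(pts[known] + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(qry, win, ignore.strand = TRUE)
  pi <- which(known)[S4Vectors::queryHits(hits)]
  gi <- S4Vectors::subjectHits(hits)

  d <- ifelse(genes$strand[gi] == "+", pts[pi] - genes$tss[gi],
              genes$tss[gi] - pts[pi])
  inside <- d >= -promoter_bp & d < L[gi] + downstream_bp
  pi <- pi[inside]; gi <- gi[inside]; d <- d[inside]

  if (policy == "nearest_tss" && length(pi)) {
    ord <- order(peaks$peak_id[pi], abs(d), genes$gene_id[gi])
    pi <- pi[ord]; gi <- gi[ord]; d <- d[ord]
    keep <- !duplicated(peaks$peak_id[pi])
    pi <- pi[keep]; gi <- gi[keep]; d <- d[keep]
  }

  region <- ifelse(d < 0L, "promoter", ifelse(d < L[gi], "body", "three_prime"))
  out <- data.frame(gene_id = genes$gene_id[gi], peak_id = peaks$peak_id[pi],
                    region = region, offset = as.integer(d),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$peak_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "factor_label") <- attr(peaks, "factor_label")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Gene ids targeted in an assignment
#' @param assignment Output of [assign_peaks_to_genes()].
#' @return Sorted character vector of unique target gene ids.
#' @export
target_genes <- function(assignment) sort(unique(assignment$gene_id))

#' Decompose two factors' target sets into binding classes
#'
#' Splits the targets of factors A and B over a common gene universe into
#' A-only, B-only and shared classes, and reports the shared class as a
#' fraction of each factor's target count.
#'
#' @param assign_a,assign_b Assignments from [assign_peaks_to_genes()], or
#'   plain character vectors of target gene ids.
#' @param universe Character vector of all assayable gene ids; must contain
#'   every target.
#' @return A list of class `target_classes` with elements `a_only`, `b_only`,
#'   `shared` (sorted id vectors), `universe_size`, `frac_shared_a`,
#'   `frac_shared_b`.
#' @export
classify_targets <- function(assign_a, assign_b, universe) {
  a <- if (is.character(assign_a)) unique(assign_a) else target_genes(assign_a)
  b <- if (is.character(assign_b)) unique(assign_b) else target_genes(assign_b)
  missing <- setdiff(union(a, b), universe)
  if (length(missing)) {
    stop_validation("target gene(s) absent from universe: ",
                    paste(utils::head(missing, 5L), collapse = ", "))
  }
  shared <- sort(intersect(a, b))
  out <- list(
    a_only = sort(setdiff(a, b)),
    b_only = sort(setdiff(b, a)),
    shared = shared,
    universe_size = length(unique(universe)),
    frac_shared_a = if (length(a)) length(shared) / length(a) else NA_real_,
    frac_shared_b = if (length(b)) length(shared) / length(b) else NA_real_
  )
  class(out) <- "target_classes"
  out
}

#' @export
print.target_classes <- function(x, ...) {
  cat(sprintf("Target classes over %d genes\n", x$universe_size))
  cat(sprintf("  A only : %d\n", length(x$a_only)))
  cat(sprintf("  B only : %d\n", length(x$b_only)))
  cat(sprintf("  shared : %d (%.1f%% of A, %.1f%% of B)\n", length(x$shared),
              100 * x$frac_shared_a, 100 * x$frac_shared_b))
  invisible(x)
}
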