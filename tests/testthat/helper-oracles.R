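## Independent oracles used across tests. These deliberately avoid the code
## paths they check: enumeration instead of phyper, literal running-sum loops
## instead of the vectorized engine, O(genes x peaks) scans instead of
## interval overlap.

## Exhaustive hypergeometric upper tail: enumerate every size-n_b subset of
## the universe, count overlaps with the fixed first-n_a set.
enum_hyper_upper <- function(n_a, n_b, k, N) {
  if (n_b == 0L) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, n_b)
  overlap <- colSums(subsets <= n_a)
  mean(overlap >= k)
}

## Log10 upper tail by direct log-space summation of hypergeometric terms.
lgamma_hyper_log10_upper <- function(n_a, n_b, k, N) {
  kk <- max(k, max(0L, n_a + n_b - N)):min(n_a, n_b)
  lt <- lchoose(n_a, kk) + lchoose(N - n_a, n_b - kk) - lchoose(N, n_b)
  m <- max(lt)
  (m + log(sum(exp(lt - m)))) / log(10)
}

## Literal GSEA running sum: step through the ranking one gene at a time.
brute_es <- function(scores, members, weight) {
  n <- length(scores)
  hit <- names(scores) %in% members
  denom_hit <- sum(abs(scores[hit])^weight)
  r <- numeric(n)
  cur <- 0
  for (i in seq_len(n)) {
    if (hit[i]) {
      inc <- if (denom_hit > 0) abs(scores[i])^weight / denom_hit else 1 / sum(hit)
      cur <- cur + inc
    } else {
      cur <- cur - 1 / (n - sum(hit))
    }
    r[i] <- cur
  }
  hi <- max(r); lo <- min(r)
  if (hi >= -lo - 1e-12) hi else lo                # magnitude ties: positive
}

## Exhaustive peak-to-gene assignment over every (gene, peak) pair.
brute_assignment <- function(peaks, genes, promoter_bp = 5000L,
                             downstream_bp = 1000L, policy = "all") {
  pts <- cotarget::peak_points(peaks)
  rows <- list()
  for (p in seq_len(nrow(peaks))) {
    cand <- list()
    for (g in seq_len(nrow(genes))) {
      if (peaks$chrom[p] != genes$chrom[g]) next
      d <- if (genes$strand[g] == "+") pts[p] - genes$tss[g] else genes$tss[g] - pts[p]
      L <- abs(genes$tes[g] - genes$tss[g])
      if (d >= -promoter_bp && d < L + downstream_bp) {
        region <- if (d < 0) "promoter" else if (d < L) "body" else "three_prime"
        cand[[length(cand) + 1L]] <- data.frame(
          gene_id = genes$gene_id[g], peak_id = peaks$peak_id[p],
          region = region, offset = as.integer(d), stringsAsFactors = FALSE)
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    if (policy == "nearest_tss") {
      cand <- cand[order(abs(cand$offset), cand$gene_id), , drop = FALSE][1L, , drop = FALSE]
    }
    rows[[length(rows) + 1L]] <- cand
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(0), peak_id = character(0),
                      region = character(0), offset = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$peak_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Small deterministic annotation: two chromosomes, mixed strands.
tiny_genes <- function() {
  gene_models(
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    strand = c("+", "-", "+", "-"),
    start = c(10000L, 30000L, 50000L, 10000L),
    end = c(12000L, 33000L, 52000L, 14000L)
  )
}

## Genotype panel with exact replicate values around stated means.
panel_fixture <- function(gene_id, wt, a, b, ab, cv = 0.05) {
  mk <- function(mu) mu * (1 + cv * c(-1, 0, 1))
  data.frame(
    gene_id = gene_id,
    genotype = rep(c("WT", "mutA", "mutB", "mutAB"), each = 3L),
    replicate = rep(1:3, 4L),
    value = c(mk(wt), mk(a), mk(b), mk(ab)),
    stringsAsFactors = FALSE
  )
}

## Assignment tables built directly (bypassing peak files) for distance tests.
offsets_assignment <- function(gene_ids, offsets, label = "f") {
  stopifnot(length(gene_ids) == length(offsets))
  out <- data.frame(gene_id = gene_ids,
                    peak_id = sprintf("%s_p%d", label, seq_along(gene_ids)),
                    region = "promoter", offset = as.integer(offsets),
                    stringsAsFactors = FALSE)
  attr(out, "factor_label") <- label
  out
}
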