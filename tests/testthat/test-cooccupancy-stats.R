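test_that("hypergeometric upper tail matches exhaustive enumeration", {
  ## worked value: P(X >= 3) for sets of 4 and 5 in a universe of 10
  expect_equal(hypergeometric_overlap(4, 5, 3, 10)$p_upper, 66 / 252,
               tolerance = 1e-14)
  expect_equal(hypergeometric_overlap(5, 5, 0, 10)$p_upper, 1)
  expect_equal(hypergeometric_overlap(10, 4, 4, 10)$p_upper, 1)  # n_a = universe

  for (N in c(5L, 8L)) {
    for (n_a in 0:N) for (n_b in 0:N) {
      for (k in max(0L, n_a + n_b - N):min(n_a, n_b)) {
        got <- hypergeometric_overlap(n_a, n_b, k, N)$p_upper
        want <- enum_hyper_upper(n_a, n_b, k, N)
        expect_equal(got, want, tolerance = 1e-12,
                     info = sprintf("N=%d a=%d b=%d k=%d", N, n_a, n_b, k))
      }
    }
  }
})

test_that("overlap statistic is symmetric, monotone in k, and validates input", {
  a <- hypergeometric_overlap(400, 120, 50, 2000)
  b <- hypergeometric_overlap(120, 400, 50, 2000)
  expect_equal(a$log10_p_upper, b$log10_p_upper, tolerance = 1e-12)
  expect_equal(a$fold_enrichment, 50 / (400 * 120 / 2000))

  ps <- vapply(0:120, function(k) {
    hypergeometric_overlap(400, 120, k, 2000)$log10_p_upper
  }, 0)
  expect_true(all(diff(ps) <= 1e-12))
  expect_true(all(ps <= 0))

  ## extreme overlaps underflow double p but keep a finite log10
  deep <- hypergeometric_overlap(5000, 5000, 5000, 30000)
  expect_equal(deep$p_upper, 0)
  expect_true(is.finite(deep$log10_p_upper) && deep$log10_p_upper < -300)

  expect_error(hypergeometric_overlap(4, 5, 6, 10), "exceeds")
  expect_error(hypergeometric_overlap(8, 8, 1, 10), "forced minimum")
})

test_that("inter-peak distances use representative points with nearest pairing", {
  a <- offsets_assignment(c("g1", "g2", "g3"), c(-150L, -400L, -100L), "A")
  b <- offsets_assignment(c("g1", "g2", "g3"), c(-350L, -400L, -120L), "B")
  d <- interpeak_distances(a, b, c("g1", "g2", "g3"))
  expect_equal(d$distance[match(c("g1", "g2", "g3"), d$gene_id)],
               c(200L, 0L, 20L))

  ## multiple factor-A peaks: nearest pairing takes the min over pairs
  a2 <- offsets_assignment(c("g1", "g1"), c(-100L, -900L), "A")
  b2 <- offsets_assignment("g1", -120L, "B")
  expect_equal(interpeak_distances(a2, b2, "g1")$distance, 20L)
  expect_equal(nrow(interpeak_distances(a2, b2, "g1", pairing = "all_pairs")), 2L)

  expect_error(interpeak_distances(a, b2, c("g1", "g2")), "lacking a peak")
})

test_that("fraction_within counts pairs at or below the threshold", {
  pairs <- data.frame(gene_id = c("g1", "g2", "g3"),
                      distance = c(0L, 100L, 300L))
  expect_equal(fraction_within(pairs, 200L), 2 / 3)
  expect_equal(fraction_within(pairs, 300L), 1)
  expect_equal(fraction_within(pairs[pairs$distance > 0, ], 0L), 0)
  expect_error(fraction_within(pairs[0, ], 200L), "no distance pairs")
})

test_that("proximity test flags planted co-binding and is seed-reproducible", {
  genes <- simulate_genome(300L, seed = 11L)
  occ <- simulate_cooccupancy(genes, 80L, 80L, 50L, sigma_shared_bp = 50,
                              seed = 12L)
  aa <- assign_peaks_to_genes(occ$peaks_a, genes)
  ab <- assign_peaks_to_genes(occ$peaks_b, genes)
  res <- proximity_permutation_test(aa, ab, occ$truth$shared,
                                    n_permutations = 999L, seed = 1L)
  expect_lte(res$p_empirical, 0.01)
  expect_equal(res$p_empirical,
               (1 + sum(res$null_statistics <= res$observed_statistic)) / 1000)

  res2 <- proximity_permutation_test(aa, ab, occ$truth$shared,
                                     n_permutations = 999L, seed = 1L)
  expect_identical(res, res2)

  frac <- proximity_permutation_test(aa, ab, occ$truth$shared,
                                     statistic = "fraction_within",
                                     threshold_bp = 200L,
                                     n_permutations = 199L, seed = 2L)
  expect_lte(frac$p_empirical, 0.05)
  expect_gte(frac$observed_statistic, 0.9)  # sigma 50 bp: nearly all within 200 bp

  expect_error(proximity_permutation_test(aa, ab, occ$truth$shared[1:3]),
               "at least 5")
  expect_error(proximity_permutation_test(aa, ab, occ$truth$shared,
                                          n_permutations = 0L),
               "n_permutations")
})

test_that("an observed statistic more extreme than every null gives p = 1/(m+1)", {
  a <- offsets_assignment(sprintf("g%d", 1:10), rep(-1000L, 10L), "A")
  b <- offsets_assignment(sprintf("g%d", 1:10), rep(-1000L, 10L), "B")
  ## identical offsets: observed distances all 0; cross-gene nulls also 0,
  ## so p = 1 in the degenerate equal-offset case
  res <- proximity_permutation_test(a, b, sprintf("g%d", 1:10),
                                    n_permutations = 99L, seed = 3L)
  expect_equal(res$observed_statistic, 0)
  expect_equal(res$p_empirical, 1)

  ## spread offsets: observed 0, nulls > 0
  set.seed(4)
  offs <- as.integer(seq(-4800L, -200L, length.out = 10L))
  a2 <- offsets_assignment(sprintf("g%d", 1:10), offs, "A")
  b2 <- offsets_assignment(sprintf("g%d", 1:10), offs, "B")
  res2 <- proximity_permutation_test(a2, b2, sprintf("g%d", 1:10),
                                     n_permutations = 999L, seed = 5L)
  expect_equal(res2$p_empirical, 1 / 1000)
})

test_that("metagene bins are placed and conserved per factor", {
  genes <- gene_models("g1", "chr1", "+", 10000L, 12001L)   # L = 2000
  a <- offsets_assignment(c("g1", "g1", "g1"), c(-2500L, 1000L, 2300L), "A")
  prof <- metagene_profile(a, genes, promoter_bp = 5000L, downstream_bp = 1000L,
                           n_promoter_bins = 50L, n_body_bins = 20L,
                           n_downstream_bins = 5L)
  expect_equal(unname(prof$counts[1, 26]), 1L)     # promoter bin index 25 (0-based)
  expect_equal(unname(prof$counts[1, 50 + 11]), 1L) # midway through body: bin 10
  expect_equal(unname(prof$counts[1, 50 + 20 + 2]), 1L) # 300 bp past TES: bin 1
  expect_equal(sum(prof$counts), 3L)
  expect_equal(sum(prof$density), 1)
})

test_that("metagene profiles conserve counts, normalize densities, ignore order", {
  genes <- simulate_genome(100L, seed = 21L)
  occ <- simulate_cooccupancy(genes, 60L, 40L, 20L, seed = 22L)
  aa <- assign_peaks_to_genes(occ$peaks_a, genes)
  ab <- assign_peaks_to_genes(occ$peaks_b, genes)
  prof <- metagene_profile(list(A = aa, B = ab), genes)
  expect_equal(unname(rowSums(prof$counts)), c(nrow(aa), nrow(ab)))
  expect_equal(unname(rowSums(prof$density)), c(1, 1))

  aa_rev <- aa[rev(seq_len(nrow(aa))), ]
  prof2 <- metagene_profile(list(A = aa_rev, B = ab), genes)
  expect_equal(prof2$counts, prof$counts)
  ## all planted points are promoter offsets
  expect_equal(sum(prof$counts[, 1:25]), nrow(aa) + nrow(ab))
})
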