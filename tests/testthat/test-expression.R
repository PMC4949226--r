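records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], log2fc = as.numeric(r[[2]]),
               p_value = as.numeric(r[[3]]), experiment_id = r[[4]],
               stringsAsFactors = FALSE)
  }))
}

test_that("merge_experiments applies the significance policies", {
  recs <- records(list("g1", 1.0, 0.01, "e1"), list("g1", 0.5, 0.20, "e2"),
                  list("g2", -1.0, 0.01, "e1"), list("g2", -0.8, 0.03, "e2"),
                  list("g3", 0.2, 0.90, "e1"), list("g3", 0.1, 0.80, "e2"))
  all_sig <- merge_experiments(recs, policy = "all_significant")
  expect_equal(rownames(all_sig$values), "g2")
  any_sig <- merge_experiments(recs, policy = "any_significant")
  expect_setequal(rownames(any_sig$values), c("g1", "g2"))

  ## gene missing from one experiment: dropped under all, NA-marked under any
  recs2 <- rbind(recs, records(list("g4", 2.0, 0.001, "e1")))
  expect_false("g4" %in% rownames(merge_experiments(recs2, policy = "all_significant")$values))
  any2 <- merge_experiments(recs2, policy = "any_significant")
  expect_true(is.na(any2$values["g4", "e2"]))

  ## four experiments, significant in all
  recs4 <- records(list("g1", 1, 0.01, "e1"), list("g1", 1, 0.02, "e2"),
                   list("g1", 1, 0.03, "e3"), list("g1", 1, 0.04, "e4"))
  expect_equal(rownames(merge_experiments(recs4, policy = "all_significant")$values),
               "g1")
  expect_error(merge_experiments(recs, alpha = 1.5), "alpha")
})

test_that("clamp_fold_changes truncates symmetrically and is idempotent", {
  fc <- merge_experiments(records(list("g1", 3.5, 0.01, "e1"),
                                  list("g2", -5.0, 0.01, "e1"),
                                  list("g3", 1.2, 0.01, "e1")),
                          policy = "any_significant")
  cl <- clamp_fold_changes(fc, 2.0)
  expect_equal(unname(cl$values[, 1]), c(2.0, -2.0, 1.2))
  expect_equal(clamp_fold_changes(cl, 2.0)$values, cl$values)
  expect_equal(cl$clamp_limit, 2.0)
  ## order-preserving
  expect_true(all(diff(order(fc$values[, 1])) == diff(order(cl$values[, 1]))))
})

test_that("sign concordance matches exact binomial enumeration", {
  ## 8 concordant of 10: two-sided p = 112/1024 by summing the binomial tails
  x <- c(rep(1, 8), rep(-1, 2))
  recs <- rbind(
    data.frame(gene_id = sprintf("g%02d", 1:10), log2fc = rep(1, 10),
               p_value = 0.01, experiment_id = "e1", stringsAsFactors = FALSE),
    data.frame(gene_id = sprintf("g%02d", 1:10), log2fc = x,
               p_value = 0.01, experiment_id = "e2", stringsAsFactors = FALSE))
  fc <- merge_experiments(recs, policy = "any_significant")
  res <- sign_concordance(fc, "e1", "e2")
  expect_equal(res$n_concordant, 8L)
  expect_equal(res$n_discordant, 2L)
  expect_equal(res$binomial_p_two_sided, 112 / 1024, tolerance = 1e-12)

  ## all concordant, n = 5: p = 2/32
  recs5 <- rbind(
    data.frame(gene_id = sprintf("g%d", 1:5), log2fc = c(1, -1, 1, 1, -1),
               p_value = 0.01, experiment_id = "e1", stringsAsFactors = FALSE),
    data.frame(gene_id = sprintf("g%d", 1:5), log2fc = c(2, -3, 1, 4, -1),
               p_value = 0.01, experiment_id = "e2", stringsAsFactors = FALSE))
  fc5 <- merge_experiments(recs5, policy = "any_significant")
  expect_equal(sign_concordance(fc5, "e1", "e2")$binomial_p_two_sided, 2 / 32,
               tolerance = 1e-12)

  ## flipping one column's sign convention swaps concordant/discordant
  flipped <- sign_concordance(fc, "e1", "e2", sign_convention = c(-1, 1))
  expect_equal(flipped$n_concordant, res$n_discordant)
  expect_equal(flipped$n_discordant, res$n_concordant)

  ## zeros are excluded from the effective count
  recs0 <- rbind(
    data.frame(gene_id = c("g1", "g2"), log2fc = c(0, 1), p_value = 0.01,
               experiment_id = "e1", stringsAsFactors = FALSE),
    data.frame(gene_id = c("g1", "g2"), log2fc = c(1, 1), p_value = 0.01,
               experiment_id = "e2", stringsAsFactors = FALSE))
  fc0 <- merge_experiments(recs0, policy = "any_significant")
  r0 <- sign_concordance(fc0, "e1", "e2")
  expect_equal(r0$n_concordant + r0$n_discordant, 1L)
})

test_that("average-linkage clustering reproduces hand-computed merges", {
  ## identical rows merge first at height 0
  fc <- list(values = rbind(g1 = c(1, 2), g2 = c(1, 2), g3 = c(9, 0)),
             pvalues = NULL, clamp_limit = NA_real_)
  class(fc) <- "fc_matrix"
  hc <- hierarchical_cluster(fc, metric = "euclidean")
  expect_equal(hc$height[1], 0)

  ## three 1-D points {0, 1, 10}: merge (0,1) at 1, then with 10 at 9.5
  fc2 <- list(values = rbind(a = c(0, 0), b = c(1, 0), c = c(10, 0)),
              pvalues = NULL, clamp_limit = NA_real_)
  class(fc2) <- "fc_matrix"
  hc2 <- hierarchical_cluster(fc2, metric = "euclidean")
  expect_equal(hc2$height, c(1, 9.5))

  ## constant row under the correlation metric is a validation error naming it
  fc3 <- list(values = rbind(flat = c(1, 1, 1), b = c(1, 2, 3)),
              pvalues = NULL, clamp_limit = NA_real_)
  class(fc3) <- "fc_matrix"
  expect_error(hierarchical_cluster(fc3, metric = "one_minus_pearson"), "flat")

  ## a single row cannot be clustered
  fc1 <- list(values = fc3$values[1, , drop = FALSE], pvalues = NULL,
              clamp_limit = NA_real_)
  class(fc1) <- "fc_matrix"
  expect_error(hierarchical_cluster(fc1, metric = "euclidean"), "at least 2")
})

test_that("correlation-metric clustering orders genes by expression pattern", {
  set.seed(9)
  up <- matrix(rep(c(1, 1.2, 0.9), 5) + rnorm(15, 0, 0.05), 5, byrow = TRUE)
  down <- -up[1:4, ] + rnorm(12, 0, 0.05)
  fc <- list(values = rbind(up, down), pvalues = NULL, clamp_limit = NA_real_)
  rownames(fc$values) <- sprintf("g%d", 1:9)
  class(fc) <- "fc_matrix"
  hc <- hierarchical_cluster(fc, metric = "one_minus_pearson")
  expect_true(all(diff(hc$height) >= -1e-12))  # monotone merges
  ## the 9-gene tree splits into the up- and down-regulated blocks
  k2 <- stats::cutree(hc, k = 2)
  expect_equal(length(unique(k2[1:5])), 1L)
  expect_equal(length(unique(k2[6:9])), 1L)
  expect_false(k2[1] == k2[6])
})

test_that("qPCR quantification helpers follow the ddCt conventions", {
  expect_equal(relative_expression(20, 20, 20, 20), 1.0)
  expect_equal(relative_expression(21, 20, 20, 20), 0.5)   # ddCt = 1
  expect_equal(relative_expression(19, 20, 21, 20), 4.0)   # ddCt = -2
  expect_equal(chip_fold_enrichment(20, 20, 20, 20), 1.0)
  expect_equal(chip_fold_enrichment(18, 21, 20, 20), 8.0)  # 3 cycles deeper
  expect_equal(chip_fold_enrichment(20, 20, 18, 21),
               1 / chip_fold_enrichment(18, 21, 20, 20))   # swap inverts
})
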