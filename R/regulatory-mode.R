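## Welch two-sample t-test on log2 values with a variance floor, so panels
## with (near-)identical replicates still yield finite statistics.
welch_log2 <- function(x, y, alternative = c("less", "greater", "two.sided"),
                       var_floor = 1e-6) {
  alternative <- match.arg(alternative)
  lx <- log2(x); ly <- log2(y)
  nx <- length(lx); ny <- length(ly)
  vx <- max(stats::var(lx), var_floor)
  vy <- max(stats::var(ly), var_floor)
  se <- sqrt(vx / nx + vy / ny)
  t <- (mean(lx) - mean(ly)) / se
  df <- se^4 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- switch(alternative,
              less = stats::pt(t, df),
              greater = stats::pt(t, df, lower.tail = FALSE),
              two.sided = 2 * stats::pt(-abs(t), df))
  list(estimate = mean(lx) - mean(ly), t = t, df = df, p = p)
}

#' Classify the regulatory mode of one gene from a genotype panel
#'
#' Decides, from WT / single-mutant A / single-mutant B / double-mutant
#' expression replicates, whether the two factors activate the gene
#' interdependently (losing either factor is as bad as losing both),
#' additively (the double mutant drops further than both singles), or not
#' at all. All tests are Welch t-tests on log2-transformed replicates with
#' one-sided alternatives in the stated direction, uncorrected within the
#' gene's four planned contrasts.
#'
#' Decision rule: (i) if neither single mutant is significantly below WT,
#' `not_coactivated`; (ii) if the double mutant is significantly below both
#' singles, `additive`; (iii) if the double is below at most one single,
#' `interdependent`, with `residual_flag` set when it is below exactly one
#' single and both singles are below WT (one factor retains residual
#' activity); (iv) when the double is below exactly one single but only one
#' single is below WT, the pattern is internally inconsistent and the call
#' is `ambiguous`.
#'
#' @param panel Long `data.frame` for one gene with columns `genotype`
#'   (`WT`, `mutA`, `mutB`, `mutAB`) and `value` (positive, WT-normalized
#'   relative expression), at least 2 replicates per genotype.
#' @param alpha Per-contrast significance level (default 0.05).
#' @return A list of class `mode_call`: `gene_id`, `label`, `residual_flag`,
#'   and `contrasts` (a `data.frame` of the four planned contrasts with
#'   log2-scale estimates and one-sided p-values).
#' @export
classify_mode <- function(panel, alpha = 0.05) {
  need <- c("WT", "mutA", "mutB", "mutAB")
  vals <- lapply(need, function(g) panel$value[panel$genotype == g])
  names(vals) <- need
  sizes <- lengths(vals)
  if (any(sizes < 2L)) {
    stop_validation("each genotype needs >= 2 replicates; missing/short: ",
                    paste(need[sizes < 2L], collapse = ", "))
  }
  if (any(unlist(vals) <= 0)) stop_validation("panel values must be positive")

  a_wt <- welch_log2(vals$mutA, vals$WT, "less")
  b_wt <- welch_log2(vals$mutB, vals$WT, "less")
  ab_a <- welch_log2(vals$mutAB, vals$mutA, "less")
  ab_b <- welch_log2(vals$mutAB, vals$mutB, "less")

  coact_a <- a_wt$p < alpha
  coact_b <- b_wt$p < alpha
  dbl_a <- ab_a$p < alpha
  dbl_b <- ab_b$p < alpha

  residual_flag <- FALSE
  if (!coact_a && !coact_b) {
    label <- "not_coactivated"
  } else if (dbl_a && dbl_b) {
    label <- "additive"
  } else if (!dbl_a && !dbl_b) {
    label <- "interdependent"
  } else if (coact_a && coact_b) {
    label <- "interdependent"
    residual_flag <- TRUE
  } else {
    label <- "ambiguous"
  }

  contrasts <- data.frame(
    contrast = c("mutA-WT", "mutB-WT", "mutAB-mutA", "mutAB-mutB"),
    estimate_log2 = c(a_wt$estimate, b_wt$estimate, ab_a$estimate, ab_b$estimate),
    p_value = c(a_wt$p, b_wt$p, ab_a$p, ab_b$p),
    stringsAsFactors = FALSE
  )
  out <- list(gene_id = if ("gene_id" %in% names(panel)) panel$gene_id[1L] else NA_character_,
              label = label, residual_flag = residual_flag,
              contrasts = contrasts, alpha = alpha)
  class(out) <- "mode_call"
  out
}

#' @export
print.mode_call <- function(x, ...) {
  cat(sprintf("%s: %s%s\n", x$gene_id, x$label,
              if (x$residual_flag) " (residual single-mutant activity)" else ""))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Classify regulatory modes for a table of genes
#'
#' Applies [classify_mode()] per gene and optionally adds a
#' Benjamini-Hochberg adjustment of each contrast's p-values across genes
#' (informational; labels always use the per-gene rule at `alpha`).
#'
#' @param panels Long `data.frame` with columns `gene_id`, `genotype`,
#'   `value` (see [read_genotype_panels()]).
#' @param alpha Per-contrast significance level.
#' @return A `data.frame` with one row per gene: `gene_id`, `label`,
#'   `residual_flag`, and the four contrast estimates/p-values.
#' @export
classify_modes <- function(panels, alpha = 0.05) {
  genes <- unique(panels$gene_id)
  rows <- lapply(genes, function(g) {
    call <- classify_mode(panels[panels$gene_id == g, , drop = FALSE], alpha)
    stats <- call$contrasts
    wide <- c(as.list(stats$estimate_log2), as.list(stats$p_value))
    names(wide) <- c(paste0("est_", gsub("-", "_", stats$contrast)),
                     paste0("p_", gsub("-", "_", stats$contrast)))
    c(list(gene_id = g, label = call$label, residual_flag = call$residual_flag),
      wide)
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
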