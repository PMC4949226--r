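## Internal coordinate convention: 0-based half-open everywhere. Conversion to
## and from 1-based closed (GFF3) happens only in this file.

#' Construct a gene-model table
#'
#' Builds the package's internal gene-model representation: one row per gene
#' with 0-based half-open coordinates and strand-aware TSS/TES anchors
#' (`tss = start` on `+`, `end - 1` on `-`; `tes` is the opposite end).
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chrom Chromosome names.
#' @param strand `"+"` or `"-"` per gene.
#' @param start,end Integer 0-based half-open coordinates, `start < end`.
#' @return A `data.frame` with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `tss`, `tes`.
#' @export
gene_models <- function(gene_id, chrom, strand, start, end) {
  gene_id <- as.character(gene_id)
  chrom <- as.character(chrom)
  strand <- as.character(strand)
  start <- as.integer(start)
  end <- as.integer(end)
  if (anyDuplicated(gene_id)) {
    stop_validation("duplicate gene_id: ",
                    paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  if (!all(strand %in% c("+", "-"))) stop_validation("strand must be '+' or '-'")
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0L) || any(start >= end)) {
    stop_validation("gene coordinates must satisfy 0 <= start < end")
  }
  data.frame(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = start, end = end,
    tss = ifelse(strand == "+", start, end - 1L),
    tes = ifelse(strand == "+", end - 1L, start),
    stringsAsFactors = FALSE
  )
}

#' Construct a peak set
#'
#' @param chrom,start,end Peak intervals, 0-based half-open.
#' @param peak_id Unique identifiers; generated from `factor_label` if `NULL`.
#' @param summit Absolute summit coordinate or `NA` when absent.
#' @param score Numeric score or `NA`.
#' @param factor_label Label for the profiled factor (e.g. `"PIF4"`).
#' @return A `data.frame` with attribute `factor_label`.
#' @export
peak_set <- function(chrom, start, end, peak_id = NULL, summit = NA,
                     score = NA, factor_label = "factor") {
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  n <- length(start)
  if (is.null(peak_id)) peak_id <- sprintf("%s_peak_%d", factor_label, seq_len(n))
  peak_id <- as.character(peak_id)
  summit <- suppressWarnings(as.integer(rep_len(summit, n)))
  score <- suppressWarnings(as.numeric(rep_len(score, n)))
  if (any(start >= end)) stop_validation("peak start must be < end")
  bad <- !is.na(summit) & (summit < start | summit >= end)
  if (any(bad)) {
    stop_validation("summit outside peak interval for: ",
                    paste(peak_id[bad], collapse = ", "))
  }
  if (anyDuplicated(peak_id)) stop_validation("duplicate peak_id within set")
  out <- data.frame(chrom = chrom, start = start, end = end, peak_id = peak_id,
                    score = score, summit = summit, stringsAsFactors = FALSE)
  attr(out, "factor_label") <- factor_label
  out
}

#' Representative point of each peak
#'
#' The summit when present, otherwise the interval midpoint
#' `floor((start + end) / 2)`. All downstream distance and assignment
#' computations use this single point.
#'
#' @param peaks A peak set (see [peak_set()]).
#' @return Integer vector of genomic positions.
#' @export
peak_points <- function(peaks) {
  ifelse(is.na(peaks$summit),
         as.integer(floor((peaks$start + peaks$end) / 2)),
         peaks$summit)
}

## ---- readers -------------------------------------------------------------

read_tab_lines <- function(path, n_fields, what) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & !grepl("^track", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(list(fields = list(), lines = integer(0)))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < n_fields)) {
    bad <- idx[which(nf < n_fields)[1L]]
    stop_validation("malformed ", what, " line ", bad, ": expected >= ",
                    n_fields, " tab-separated fields, got ", nf[which(nf < n_fields)[1L]])
  }
  list(fields = fields, lines = idx)
}

num_field <- function(fields, i, lines, what) {
  x <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
  if (anyNA(x)) {
    stop_validation("malformed ", what, " line ", lines[which(is.na(x))[1L]],
                    ": non-numeric field ", i)
  }
  x
}

chr_field <- function(fields, i) vapply(fields, `[[`, "", i)

#' Read gene models from GFF3, BED12 or TSV
#'
#' GFF3 coordinates (1-based closed) are converted to the internal 0-based
#' half-open convention; BED and TSV inputs are already 0-based half-open.
#' For GFF3, rows of type `gene` are used (all rows when no `gene` rows
#' exist) and `gene_id` is taken from the `ID` attribute, falling back to
#' `Name`.
#'
#' @param path Input file.
#' @param format One of `"gff3"`, `"bed12"`, `"tsv"`. TSV expects a header
#'   with columns `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @return A gene-model `data.frame`, see [gene_models()].
#' @export
read_gene_models <- function(path, format = c("gff3", "bed12", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("file not found: ", path)
  if (format == "gff3") {
    parsed <- read_tab_lines(path, 9L, "GFF3")
    gr <- rtracklayer::import(path, format = "gff3")
    if ("type" %in% names(S4Vectors::mcols(gr)) &&
        any(as.character(gr$type) == "gene")) {
      gr <- gr[as.character(gr$type) == "gene"]
    }
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else NULL
    if (is.null(ids) || anyNA(ids)) {
      nm <- if (!is.null(gr$Name)) as.character(gr$Name) else NULL
      if (is.null(ids)) ids <- nm else ids[is.na(ids)] <- nm[is.na(ids)]
    }
    if (is.null(ids) || anyNA(ids)) stop_validation("GFF3 gene records need an ID or Name attribute")
    return(gene_models(sub("^gene:", "", ids), as.character(GenomicRanges::seqnames(gr)),
                       as.character(GenomicRanges::strand(gr)),
                       GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr)))
  }
  if (format == "bed12") {
    p <- read_tab_lines(path, 12L, "BED12")
    return(gene_models(chr_field(p$fields, 4L), chr_field(p$fields, 1L),
                       chr_field(p$fields, 6L),
                       num_field(p$fields, 2L, p$lines, "BED12"),
                       num_field(p$fields, 3L, p$lines, "BED12")))
  }
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(tab))) {
    stop_validation("gene TSV needs columns: ", paste(need, collapse = ", "))
  }
  gene_models(tab$gene_id, tab$chrom, tab$strand, tab$start, tab$end)
}

#' Write gene models
#'
#' @param genes Gene-model table.
#' @param path Output file.
#' @param format `"gff3"`, `"bed12"` or `"tsv"`.
#' @export
write_gene_models <- function(genes, path, format = c("gff3", "bed12", "tsv")) {
  format <- match.arg(format)
  if (format == "gff3") {
    lines <- c("##gff-version 3",
               sprintf("%s\tcotarget\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$chrom, genes$start + 1L, genes$end,
                       genes$strand, genes$gene_id))
    writeLines(lines, path)
  } else if (format == "bed12") {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t1\t%d,\t0,",
                     genes$chrom, genes$start, genes$end, genes$gene_id,
                     genes$strand, genes$start, genes$end,
                     genes$end - genes$start)
    writeLines(lines, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header_comment("gene_models"), con)
    write.table(genes[, c("gene_id", "chrom", "strand", "start", "end")],
                con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read ChIP peaks from BED6 or ENCODE narrowPeak
#'
#' narrowPeak column 10 holds the summit offset from `start`; `-1` means
#' absent. BED6 peaks carry no summit; downstream code falls back to the
#' interval midpoint (see [peak_points()]).
#'
#' @param path Input file.
#' @param dialect `"narrowpeak"` or `"bed6"`.
#' @param factor_label Label for the profiled factor.
#' @return A peak set, see [peak_set()].
#' @export
read_peaks <- function(path, dialect = c("narrowpeak", "bed6"),
                       factor_label = "factor") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_validation("file not found: ", path)
  ncol_need <- if (dialect == "narrowpeak") 10L else 6L
  p <- read_tab_lines(path, ncol_need, dialect)
  if (length(p$lines) == 0L) {
    return(peak_set(character(0), integer(0), integer(0),
                    factor_label = factor_label))
  }
  chrom <- chr_field(p$fields, 1L)
  start <- as.integer(num_field(p$fields, 2L, p$lines, dialect))
  end <- as.integer(num_field(p$fields, 3L, p$lines, dialect))
  name <- chr_field(p$fields, 4L)
  score <- num_field(p$fields, 5L, p$lines, dialect)
  ids <- ifelse(name == "." | name == "",
                sprintf("%s_peak_%d", factor_label, seq_along(start)), name)
  summit <- rep(NA_integer_, length(start))
  if (dialect == "narrowpeak") {
    off <- as.integer(num_field(p$fields, 10L, p$lines, "narrowPeak"))
    bad <- off >= (end - start)
    if (any(bad)) {
      stop_validation("narrowPeak line ", p$lines[which(bad)[1L]],
                      ": summit offset >= peak width")
    }
    summit <- ifelse(off >= 0L, start + off, NA_integer_)
  }
  peak_set(chrom, start, end, peak_id = ids, summit = summit, score = score,
           factor_label = factor_label)
}

#' Write peaks in BED6 or narrowPeak
#'
#' @param peaks Peak set.
#' @param path Output file.
#' @param dialect `"narrowpeak"` or `"bed6"`.
#' @export
write_peaks <- function(peaks, path, dialect = c("narrowpeak", "bed6")) {
  dialect <- match.arg(dialect)
  score <- ifelse(is.na(peaks$score), 0, peaks$score)
  if (dialect == "narrowpeak") {
    off <- ifelse(is.na(peaks$summit), -1L, peaks$summit - peaks$start)
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.\t0\t-1\t-1\t%d",
                     peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                     format(score, trim = TRUE, scientific = FALSE), off)
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.",
                     peaks$chrom, peaks$start, peaks$end, peaks$peak_id,
                     format(score, trim = TRUE, scientific = FALSE))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Accepts a per-experiment TSV with header `gene_id`, `log2fc`, `p_value`,
#' or a long-format table that additionally carries an `experiment_id`
#' column.
#'
#' @param path Input TSV.
#' @param experiment_id Experiment label used when the file has no
#'   `experiment_id` column; defaults to the file name without extension.
#' @return A `data.frame` with columns `gene_id`, `log2fc`, `p_value`,
#'   `experiment_id`.
#' @export
read_expression_table <- function(path, experiment_id = NULL) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene_id", "log2fc", "p_value")
  if (!all(need %in% names(tab))) {
    stop_validation("expression TSV needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(tab) == 0L) {
    return(data.frame(gene_id = character(0), log2fc = numeric(0),
                      p_value = numeric(0), experiment_id = character(0),
                      stringsAsFactors = FALSE))
  }
  log2fc <- suppressWarnings(as.numeric(tab$log2fc))
  p <- suppressWarnings(as.numeric(tab$p_value))
  if (anyNA(log2fc) || anyNA(p)) {
    stop_validation("non-numeric log2fc or p_value in ", path)
  }
  if (any(p < 0 | p > 1)) stop_validation("p_value outside [0,1] in ", path)
  exp_id <- if ("experiment_id" %in% names(tab)) tab$experiment_id else {
    if (is.null(experiment_id)) experiment_id <- sub("\\.[^.]+$", "", basename(path))
    rep(experiment_id, nrow(tab))
  }
  data.frame(gene_id = tab$gene_id, log2fc = log2fc, p_value = p,
             experiment_id = exp_id, stringsAsFactors = FALSE)
}

#' Write a differential-expression table
#' @param records Expression records (long format).
#' @param path Output TSV.
#' @export
write_expression_table <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_comment("expression"), con)
  write.table(format_doubles(records), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

## 17 significant digits: doubles survive the text round trip bit-exactly.
format_doubles <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Read gene sets in GMT format
#'
#' One set per line: `set_id <tab> description <tab> gene1 <tab> gene2 ...`.
#'
#' @param path GMT file.
#' @return Named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) stop_validation("malformed GMT line ", short[1L])
  stats::setNames(lapply(fields, function(f) f[-(1:2)]),
                  vapply(fields, `[[`, "", 1L))
}

#' Write gene sets in GMT format
#' @param sets Named list of gene-id vectors.
#' @param path Output file.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(id) {
    paste(c(id, id, sets[[id]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Read genotype expression panels
#'
#' Long-format TSV with header `gene_id`, `genotype`, `replicate`, `value`;
#' values are WT-normalized relative expression (positive).
#'
#' @param path Input TSV.
#' @return A long `data.frame`.
#' @export
read_genotype_panels <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  need <- c("gene_id", "genotype", "replicate", "value")
  if (!all(need %in% names(tab))) {
    stop_validation("panel TSV needs columns: ", paste(need, collapse = ", "))
  }
  tab$value <- suppressWarnings(as.numeric(tab$value))
  if (anyNA(tab$value) || any(tab$value <= 0)) {
    stop_validation("panel values must be positive numbers")
  }
  tab[, need]
}

#' Write genotype expression panels
#' @param panels Long-format panel table.
#' @param path Output TSV.
#' @export
write_genotype_panels <- function(panels, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_comment("genotype_panels"), con)
  write.table(format_doubles(panels), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

header_comment <- function(what, params = NULL) {
  v <- tryCatch(as.character(utils::packageVersion("cotarget")),
                error = function(e) "dev")
  extra <- if (length(params)) {
    paste0(" ", paste(names(params), unlist(params), sep = "=", collapse = " "))
  } else ""
  sprintf("# cotarget %s %s%s", v, what, extra)
}
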