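test_that("GFF3 gene models convert 1-based closed to internal 0-based half-open", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gPlus",
    "chr1\tsrc\tgene\t2001\t3000\t.\t-\t.\tID=gMinus"
  ), path)
  g <- read_gene_models(path, "gff3")
  gp <- g[g$gene_id == "gPlus", ]
  expect_equal(gp$start, 1000L)
  expect_equal(gp$end, 2000L)
  expect_equal(gp$tss, 1000L)
  expect_equal(gp$tes, 1999L)
  gm <- g[g$gene_id == "gMinus", ]
  expect_equal(gm$tss, 2999L)
  expect_equal(gm$tes, 2000L)
})

test_that("BED12 strand orientation sets TSS/TES and duplicates are rejected", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste(c("chr1", 1000L, 2000L, "gM", 0, "-", 1000L, 2000L, 0, 1,
                     "1000,", "0,"), collapse = "\t"), path)
  g <- read_gene_models(path, "bed12")
  expect_equal(g$tss, 1999L)
  expect_equal(g$tes, 1000L)

  dup <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1",
               "chr1\tsrc\tgene\t200\t300\t.\t+\t.\tID=g1"), dup)
  expect_error(read_gene_models(dup, "gff3"), "duplicate gene_id")
})

test_that("malformed lines raise parse errors naming the line number", {
  bad <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t300\tp1\t50\t.\t1\t-1\t-1\t50",
               "chr1\t400\t500"), bad)
  expect_error(read_peaks(bad, "narrowpeak"), "line 2")
})

test_that("narrowPeak summit offsets map to absolute summits, -1 means absent", {
  path <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t300\tp1\t50\t.\t1\t-1\t-1\t50",
               "chr1\t400\t600\tp2\t10\t.\t1\t-1\t-1\t-1"), path)
  pk <- read_peaks(path, "narrowpeak", factor_label = "A")
  expect_equal(pk$summit, c(150L, NA_integer_))
  expect_equal(peak_points(pk), c(150L, 500L))   # midpoint fallback

  off_bad <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t100\t300\tp1\t50\t.\t1\t-1\t-1\t200", off_bad)
  expect_error(read_peaks(off_bad, "narrowpeak"), "summit offset")
})

test_that("BED6 peaks carry score from column 5 and no summit", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t300\tp1\t42\t.", path)
  pk <- read_peaks(path, "bed6")
  expect_true(is.na(pk$summit))
  expect_equal(pk$score, 42)
})

test_that("expression tables parse, validate p-values, and accept empty files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlog2fc\tp_value", "AT4G37580\t1.7\t0.004"), path)
  rec <- read_expression_table(path, experiment_id = "pifq")
  expect_equal(rec$gene_id, "AT4G37580")
  expect_equal(rec$log2fc, 1.7)
  expect_equal(rec$experiment_id, "pifq")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlog2fc\tp_value", "g1\t1.0\t1.5"), bad)
  expect_error(read_expression_table(bad), "outside")

  nonnum <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlog2fc\tp_value", "g1\t1.0\txx"), nonnum)
  expect_error(read_expression_table(nonnum), "non-numeric")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene_id\tlog2fc\tp_value", empty)
  expect_equal(nrow(read_expression_table(empty)), 0L)
})

test_that("every format round-trips bit-exactly", {
  genes <- tiny_genes()
  for (fmt in c("gff3", "bed12", "tsv")) {
    path <- withr::local_tempfile()
    write_gene_models(genes, path, fmt)
    back <- read_gene_models(path, fmt)
    expect_equal(back, genes, info = fmt)
  }

  pk <- peak_set(chrom = c("chr1", "chr1"), start = c(100L, 400L),
                 end = c(300L, 600L), summit = c(150L, NA),
                 score = c(5, 7), factor_label = "A")
  for (dialect in c("narrowpeak", "bed6")) {
    path <- withr::local_tempfile()
    write_peaks(pk, path, dialect)
    back <- read_peaks(path, dialect, factor_label = "A")
    expect_equal(back$start, pk$start, info = dialect)
    expect_equal(back$end, pk$end, info = dialect)
    expect_equal(back$peak_id, pk$peak_id, info = dialect)
    expect_equal(back$score, pk$score, info = dialect)
  }
  np <- withr::local_tempfile()
  write_peaks(pk, np, "narrowpeak")
  expect_equal(read_peaks(np, "narrowpeak", "A")$summit, pk$summit)

  ex <- data.frame(gene_id = c("g1", "g2"), log2fc = c(1.25, -0.5),
                   p_value = c(0.01, 0.2), experiment_id = "e1",
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile()
  write_expression_table(ex, path)
  expect_equal(read_expression_table(path), ex)

  sets <- list(s1 = c("g1", "g2"), s2 = c("g3"))
  path <- withr::local_tempfile()
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)

  pn <- panel_fixture("g1", 1, 0.3, 0.3, 0.3)
  path <- withr::local_tempfile()
  write_genotype_panels(pn, path)
  expect_equal(read_genotype_panels(path), pn)
})

test_that("GFF3 coordinate conversion is an involution", {
  path1 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t5001\t7000\t.\t+\t.\tID=g1",
               "chr2\tsrc\tgene\t1\t900\t.\t-\t.\tID=g2"), path1)
  g <- read_gene_models(path1, "gff3")
  path2 <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(g, path2, "gff3")
  reread <- read_gene_models(path2, "gff3")
  expect_identical(reread, g)
  ## 1-based coordinates in the re-written file match the original
  orig <- read.table(path1, sep = "\t")
  new <- read.table(path2, sep = "\t")
  expect_equal(new[, c(1, 4, 5, 7)], orig[, c(1, 4, 5, 7)])
})

test_that("peak and gene constructors enforce their invariants", {
  expect_error(peak_set("chr1", 100L, 100L), "start must be <")
  expect_error(peak_set("chr1", 100L, 300L, summit = 300L), "summit outside")
  expect_error(gene_models("g1", "chr1", "+", 50L, 50L), "start < end")
  expect_error(gene_models(c("g", "g"), "chr1", c("+", "+"), c(0L, 10L),
                           c(5L, 20L)), "duplicate")
})
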