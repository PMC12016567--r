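test_that("BED and narrowPeak files parse to 0-based half-open peak tibbles", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100", f)
  p <- read_peaks(f)
  expect_equal(nrow(p), 1L)
  expect_equal(p$chrom, "chr1")
  expect_equal(p$start, 0)
  expect_equal(p$end, 100)

  writeLines(character(0), f)
  expect_equal(nrow(read_peaks(f)), 0L)

  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr2\t500\t900\tpeak1\t100\t.\t7.5\t3.2\t2.9\t200", np)
  q <- read_peaks(np)
  expect_equal(q$score, 7.5)   # narrowPeak signalValue, column 7

  writeLines(c("chr1\t0\t100", "chr1\t50"), f)
  expect_error(read_peaks(f), "line 2")
  writeLines("chr1\t100\t50", f)
  expect_error(read_peaks(f), "line 1")
})

test_that("peak reading keeps condition labels and harmonizes chr prefixes", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("5\t10\t20", "chr4\t0\t10"), f)
  p <- read_peaks(f, condition = "tumor", assay = "CTCF", harmonize_chr = TRUE)
  expect_setequal(p$chrom, c("chr5", "chr4"))
  expect_equal(unique(p$condition), "tumor")
  expect_equal(unique(p$assay), "CTCF")
})

test_that("GTF gene models convert coordinates and union exon lengths", {
  f <- withr::local_tempfile(fileext = ".gtf")
  genes <- tibble::tibble(gene_id = c("gA", "gB", "gC"),
                          chrom = "chr1", strand = c("+", "-", "+"),
                          start = c(1, 201, 401), end = c(150, 300, 420))
  exons <- list(gA = rbind(c(1, 100), c(51, 150)),   # union = 150 bp
                gB = rbind(c(201, 300)),
                gC = rbind(c(401, 401)))             # single 1-bp exon
  write_test_gtf(f, genes, exons)
  gm <- read_gene_models(f)
  expect_equal(gm$exonic_length[gm$gene_id == "gA"], 150)
  expect_equal(gm$exonic_length[gm$gene_id == "gC"], 1)
  # GTF start shifts by -1, end is preserved
  expect_equal(gm$start[gm$gene_id == "gA"], 0)
  expect_equal(gm$end[gm$gene_id == "gA"], 150)
  # minus-strand TSS is the last covered base, 0-based
  expect_equal(gm$tss[gm$gene_id == "gB"], 299)
  expect_equal(gm$tss[gm$gene_id == "gA"], 0)
})

test_that("genes without exon rows fall back to span length with a warning", {
  f <- withr::local_tempfile(fileext = ".gtf")
  genes <- tibble::tibble(gene_id = c("gA", "gB"), chrom = "chr1",
                          strand = "+", start = c(1, 1001), end = c(100, 1100))
  write_test_gtf(f, genes, list(gA = rbind(c(1, 100))))
  expect_warning(gm <- read_gene_models(f), "without exon")
  expect_equal(gm$exonic_length[gm$gene_id == "gB"], 100)
})

test_that("make_bins tiles chromosomes with a short final bin", {
  b <- make_bins(c(chrA = 100000), 40000)
  expect_equal(nrow(b), 3L)
  expect_equal(b$start[3], 80000)
  expect_equal(b$end[3], 100000)

  expect_equal(nrow(make_bins(c(chrA = 40000), 40000)), 1L)

  b2 <- make_bins(c(chrA = 100000, chrB = 80000), 40000)
  expect_equal(b2$bin, 1:5)
  expect_equal(b2$chrom, c("chrA", "chrA", "chrA", "chrB", "chrB"))

  expect_error(make_bins(c(chrA = 0), 40000), "zero-length")
  expect_error(make_bins(c(chrA = 100), -1), "resolution")
})

test_that("interval_overlap honors half-open adjacency and tolerance", {
  a <- tibble::tibble(chrom = "c", start = 0, end = 10)
  b <- tibble::tibble(chrom = "c", start = 10, end = 20)
  expect_equal(nrow(interval_overlap(a, b, 0)), 0L)
  expect_equal(nrow(interval_overlap(a, b, 1)), 1L)
  ident <- tibble::tibble(chrom = "c", start = c(0, 100), end = c(10, 120))
  ov <- interval_overlap(ident, ident, 0)
  expect_true(all(paste(1:2, 1:2) %in% paste(ov$idx_a, ov$idx_b)))
  expect_error(interval_overlap(a, b, -1), "tolerance")
})

test_that("interval_overlap agrees with an all-pairs brute force", {
  set.seed(11)
  for (rep in 1:5) {
    a <- tibble::tibble(chrom = sample(c("c1", "c2"), 30, TRUE),
                        start = sample(0:500, 30, TRUE))
    a$end <- a$start + sample(1:50, 30, TRUE)
    b <- tibble::tibble(chrom = sample(c("c1", "c2"), 25, TRUE),
                        start = sample(0:500, 25, TRUE))
    b$end <- b$start + sample(1:50, 25, TRUE)
    tol <- sample(0:20, 1)
    expect_equal(interval_overlap(a, b, tol), brute_force_overlap(a, b, tol))
  }
})

test_that("gc_content counts G+C over non-N bases", {
  fa <- withr::local_tempfile(fileext = ".fa")
  write_fasta(list(chrA = "GGCCATGCANGCNNNN"), fa)
  iv <- tibble::tibble(chrom = "chrA",
                       start = c(0, 4, 8, 12), end = c(4, 8, 12, 16))
  gc <- gc_content(iv, fa)
  expect_equal(gc[1], 1.0)        # GGCC
  expect_equal(gc[2], 0.5)        # ATGC
  expect_equal(gc[3], 2 / 3)      # ANGC: N excluded from the denominator
  expect_true(is.na(gc[4]))       # all N
  expect_error(gc_content(tibble::tibble(chrom = "chrZ", start = 0, end = 1), fa),
               "chrZ")
})

test_that("bedGraph tracks round-trip per-bin values", {
  bins <- make_bins(c(chrA = 120000), 40000)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(c(1, 2, 3), bins, f)
  expect_length(readLines(f), 3L)
  expect_equal(read_bedgraph(f, bins), c(1, 2, 3))

  write_bedgraph(c(1.123456, NA, -0.25), bins, f)
  expect_length(readLines(f), 2L)
  expect_equal(read_bedgraph(f, bins), c(1.123456, NA, -0.25))

  expect_error(write_bedgraph(c(1, 2), bins, f), "match the bin table")
})
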