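test_that("BED-family parsing follows the 0-based half-open standard", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=test", "# comment",
               "chr9\t5449462\t5449962"), f)
  p <- read_peaks(f, "bed3")
  expect_equal(format_region(p), "chr9:5449463-5449962")
  expect_equal(width(p), 500L)

  np <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t100\t200\tpk1\t500\t+\t7.5\t-1\t-1\t-1",
               "chr1\t300\t400\tpk2\t500\t-\t2.5\t-1\t-1\t25"), np)
  g <- read_peaks(np, "narrowPeak")
  expect_identical(mcols(g)$summit, c(NA_integer_, 25L))
  expect_equal(mcols(g)$signal, c(7.5, 2.5))
  expect_identical(as.character(strand(g)), c("+", "-"))
})

test_that("malformed rows fail with the offending line number", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t50\t50"), f)
  expect_error(read_peaks(f, "bed3"), "line 2")
  writeLines(c("chr1\t10"), f)
  expect_error(read_peaks(f, "bed3"), "line 1")
  expect_error(peaks("chr1", 10, 10), "end > start")
})

test_that("read_peaks is the inverse of write_peaks per dialect", {
  p <- peaks(c("chr1", "chr2"), c(0L, 999L), c(150L, 2000L),
             name = c("a", "b"), signal = c(3, 8),
             summit = c(10L, NA), strand = c("+", "*"))
  for (d in c("bed3", "bed6", "narrowPeak")) {
    f <- withr::local_tempfile(fileext = ".bed")
    write_peaks(p, f, d)
    q <- read_peaks(f, d)
    expect_identical(ranges(q), ranges(p), info = d)
    expect_identical(seqnames(q), seqnames(p), info = d)
    if (d != "bed3") {  # bed3 carries no strand
      expect_identical(mcols(q)$name, mcols(p)$name, info = d)
      expect_identical(as.character(strand(q)), as.character(strand(p)),
                       info = d)
    }
    if (d == "narrowPeak") {
      expect_equal(mcols(q)$signal, mcols(p)$signal)
      expect_identical(mcols(q)$summit, mcols(p)$summit)
    }
  }
})

test_that("consensus matches the worked 3-sample example", {
  ps <- list(peaks("chrT", 0L, 100L), peaks("chrT", 50L, 150L),
             peaks("chrT", 60L, 90L))
  r <- consensus_regions(ps, min_support = 1.0)
  # all three cover exactly 0-based [60, 90)
  expect_equal(start(r) - 1L, 60L)
  expect_equal(end(r), 90L)
  expect_equal(mcols(r)$support, 3L)
})

test_that("a single sample returns its merged peaks verbatim", {
  p <- peaks(rep("chrT", 3), c(10L, 50L, 200L), c(60L, 100L, 300L))
  r <- consensus_regions(list(p), min_support = 0.3)
  expect_equal(start(r), c(11L, 201L))
  expect_equal(end(r), c(100L, 300L))
})

test_that("fixed-width standardization centres on the run midpoint", {
  # run at 0-based [6000, 6030): midpoint 6015 -> window [5765, 6265)
  ps <- list(peaks("chrT", 6000L, 6030L))
  r <- consensus_regions(ps, 1.0, fixed_width = 500)
  expect_equal(start(r) - 1L, 5765L)
  expect_equal(end(r), 6265L)
  expect_equal(width(r), 500L)
  # trimmed at the chromosome end when sizes are known
  r2 <- consensus_regions(ps, 1.0, fixed_width = 500,
                          chrom_sizes = c(chrT = 6100L))
  expect_equal(end(r2), 6100L)
})

test_that("support counts distinct samples, not peaks", {
  dup <- peaks(rep("chrT", 3), c(100L, 100L, 100L), c(200L, 200L, 200L))
  other <- peaks("chrT", 500L, 600L)
  # one sample with triplicated peak + one sample elsewhere: no base
  # reaches 2-sample support
  r <- consensus_regions(list(dup, other), min_support = 1.0)
  expect_length(r, 0)
})

test_that("consensus equals the per-base oracle and ignores sample order", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    len <- 3000L
    ps <- random_peak_sets(n, len)
    for (ms in c(0.5, 0.9, 1.0)) {
      got <- consensus_regions(ps, ms)
      exp <- oracle_consensus(ps, ms, len)
      expect_equal(start(got), exp$start)
      expect_equal(end(got), exp$end)
      # permutation invariance + sorted, disjoint output
      perm <- consensus_regions(ps[sample(n)], ms)
      expect_identical(granges(perm), granges(got))
      expect_false(is.unsorted(start(got)))
      if (length(got) > 1) expect_true(isDisjoint(got))
    }
  }
  expect_error(consensus_regions(list(peaks("c", 0L, 5L)), 0), "min_support")
  expect_error(consensus_regions(list(peaks("c", 0L, 5L)), 1.2), "min_support")
})

test_that("promoter assignment is strand-aware and nearest-TSS", {
  genes <- data.frame(gene = c("GA", "GB", "GMINUS"),
                      chrom = "chrT", tss = c(10000L, 10900L, 50000L),
                      strand = c("+", "+", "-"))
  pw <- promoter_windows(genes, upstream = 2000, downstream = 500)
  # minus-strand window extends rightward of the TSS by `upstream`
  expect_equal(start(pw["GMINUS"]), 50000L - 500L + 1L)
  expect_equal(end(pw["GMINUS"]), 50000L + 2000L)

  # region equal to GA's promoter window maps to GA
  reg <- granges(pw["GA"])
  strand(reg) <- "*"
  a <- assign_promoters(reg, genes)
  expect_equal(a$gene, "GA")
  expect_equal(a$distance, abs((start(reg) + end(reg)) %/% 2L - 10000L))

  # a region between GA and GB overlaps both promoters; nearer TSS wins
  mid <- GRanges("chrT", IRanges(10380, 10420))  # midpoint 10400
  a2 <- assign_promoters(mid, genes)
  expect_equal(a2$gene, "GA")  # |10400-10000| = 400 < |10400-10900| = 500

  # unmapped regions are flagged, not dropped
  far <- GRanges("chrT", IRanges(900000, 900100))
  a3 <- assign_promoters(c(mid, far), genes)
  expect_equal(nrow(a3), 2)
  expect_true(is.na(a3$gene[2]))

  # exact distance tie breaks to the lexicographically smaller symbol
  tie_genes <- data.frame(gene = c("ZZ", "AA"), chrom = "chrT",
                          tss = c(1000L, 2000L), strand = "+")
  tied <- GRanges("chrT", IRanges(1400, 1600))  # midpoint 1500
  expect_equal(assign_promoters(tied, tie_genes)$gene, "AA")
})

test_that("feature classes partition the regions with promoter priority", {
  genes <- data.frame(gene = "G1", chrom = "chrT", tss = 5000L, strand = "+")
  exons <- GRanges("chrT", IRanges(5400, 6000))
  introns <- GRanges("chrT", IRanges(6001, 9000))
  regions <- GRanges("chrT", IRanges(c(5300, 6500, 200000), width = 200))
  ann <- annotate_features(regions, genes, exons, introns)
  expect_equal(ann$classes, c("promoter", "intron", "intergenic"))
  expect_equal(sum(ann$counts), length(regions))
  # promoter beats exon when a region overlaps both
  both <- GRanges("chrT", IRanges(5400, 5600))
  expect_equal(annotate_features(both, genes, exons, introns)$classes,
               "promoter")
})
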