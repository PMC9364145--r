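test_that("pwm_from_counts applies the pseudocount arithmetic", {
  counts <- matrix(c(8, 2, 0, 0), nrow = 4, ncol = 3,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pwm_from_counts(counts, pseudocount = 1)
  expect_equal(unname(pwm$matrix[, 1]), c(9, 3, 1, 1) / 14)
  expect_true(all(abs(colSums(pwm$matrix) - 1) < 1e-9))
  # single-sequence counts, zero pseudocount -> indicator columns
  ind <- pwm_from_counts(matrix(c(1, 0, 0, 0), 4, 2,
                                dimnames = list(c("A", "C", "G", "T"), NULL)),
                         pseudocount = 0)
  expect_equal(unname(ind$matrix[, 1]), c(1, 0, 0, 0))
  # uniform counts -> uniform columns
  uni <- pwm_from_counts(matrix(5, 4, 3,
                                dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_true(all(abs(uni$matrix - 0.25) < 1e-12))
  expect_error(pwm_from_counts(matrix(0, 4, 2), pseudocount = 0),
               "all-zero")
})

test_that("the consensus sequence is the unique maximal-score hit", {
  pwm <- random_pwm(8)
  cons <- pwm_consensus(pwm)
  hits <- scan_pwm(cons, pwm, threshold_bits = -Inf)
  top <- hits[which.max(hits$score), ]
  expect_equal(top$start, 1L)
  expect_equal(top$strand, "+")
  expect_equal(top$score, pwm_max_score(pwm))
})

test_that("scan matches the exhaustive oracle on random instances", {
  set.seed(17)
  for (rep in 1:12) {
    L <- sample(4:15, 1)
    pwm <- random_pwm(L)
    n <- sample(100:400, 1)
    seqc <- paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                         prob = c(rep(0.24, 4), 0.04)), collapse = "")
    thr <- 0.3 * pwm_max_score(pwm)
    got <- scan_pwm(seqc, pwm, threshold_bits = thr)
    exp <- oracle_scan(seqc, pwm, thr)
    expect_equal(nrow(got), nrow(exp))
    if (nrow(exp)) {
      exp <- exp[order(exp$start, exp$strand), ]
      expect_equal(got$start, exp$start)
      expect_equal(got$strand, exp$strand)
      expect_equal(got$score, exp$score, tolerance = 1e-12)
    }
  }
})

test_that("hit sets on a sequence and its reverse complement mirror", {
  set.seed(23)
  pwm <- random_pwm(6)
  n <- 300
  seqc <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqc)))
  thr <- 0.3 * pwm_max_score(pwm)
  fwd <- scan_pwm(seqc, pwm, thr)
  rev <- scan_pwm(rc, pwm, thr)
  # a + hit at [s, e] on the forward sequence is a - hit at the mirrored
  # window on the reverse complement, and vice versa
  mirror <- data.frame(start = n - rev$end + 1L, end = n - rev$start + 1L,
                       strand = ifelse(rev$strand == "+", "-", "+"),
                       score = rev$score)
  mirror <- mirror[order(mirror$start, mirror$strand), ]
  expect_equal(fwd$start, mirror$start)
  expect_equal(fwd$strand, mirror$strand)
  expect_equal(fwd$score, mirror$score, tolerance = 1e-12)
})

test_that("scan edge rules: short sequences and N windows", {
  pwm <- random_pwm(10)
  expect_equal(nrow(scan_pwm("ACGT", pwm)), 0L)  # motif longer than sequence
  seq_n <- paste0(paste(rep("N", 10), collapse = ""), pwm_consensus(pwm))
  hits <- scan_pwm(seq_n, pwm, threshold_bits = -1000)
  expect_false(any(hits$start <= 10 & hits$strand == "+" &
                   hits$start > 1))  # windows containing N are skipped
  expect_true(any(hits$start == 11))
})

test_that("JASPAR PFM text round-trips through the reader", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0001.1 TESTMOTIF",
               "A [ 4 19  0  2 ]",
               "C [16  0  1  2 ]",
               "G [ 0  1 18  2 ]",
               "T [ 0  0  1 14 ]"), f)
  pwms <- read_jaspar_pfm(f, pseudocount = 0)
  expect_length(pwms, 1)
  pwm <- pwms[[1]]
  expect_equal(pwm$name, "MA0001.1 TESTMOTIF")
  expect_equal(ncol(pwm$matrix), 4)
  expect_equal(unname(pwm$matrix["A", 1]), 4 / 20)
  expect_equal(pwm_consensus(pwm), "CAGT")
})

test_that("chip overlap degenerate cases behave as specified", {
  regions <- GRanges("chrT", IRanges(c(1001, 5001), width = 500))
  sizes <- c(chrT = 100000L)
  # no chip peaks: observed 0, p = 1
  none <- chip_overlap_test(peaks(character(), integer(), integer()),
                            regions, sizes, n_perm = 100, seed = 1)
  expect_equal(none$observed, 0)
  expect_equal(none$p_value, 1)
  # chip covering the whole chromosome: observed = all, null always ties
  all_cov <- peaks("chrT", 0L, 100000L, signal = 1)
  sat <- chip_overlap_test(all_cov, regions, sizes, n_perm = 100, seed = 1)
  expect_equal(sat$observed, 2)
  expect_equal(sat$p_value, 1)
  expect_error(chip_overlap_test(all_cov, regions, sizes, n_perm = 50),
               ">= 100")
  wide <- GRanges("chrT", IRanges(1, 200000))
  expect_error(chip_overlap_test(all_cov, wide, sizes, 100), "wider")
})

test_that("permutation p agrees with the analytic placement probability", {
  # single 500 bp chip peak, single 500 bp region on a sparse chromosome:
  # null overlap chance = (w_r + w_c - 1) / (L - w_r + 1)
  L <- 200000L
  w <- 500L
  chip <- peaks("chrT", 99750L, 99750L + w, signal = 1)
  region <- GRanges("chrT", IRanges(99800, 99800 + w - 1L))
  res <- chip_overlap_test(chip, region, c(chrT = L), n_perm = 2000,
                           seed = 42)
  expect_equal(res$observed, 1)
  p0 <- (2 * w - 1) / (L - w + 1)  # ~ 0.005
  expected_p <- (1 + 2000 * p0) / 2001
  mc_sd <- sqrt(2000 * p0 * (1 - p0)) / 2001
  expect_lt(abs(res$p_value - expected_p), 4 * mc_sd + 1e-6)
  expect_lt(res$p_value, 0.05)
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(31)
  L <- 50000L
  chip <- peaks(rep("chrT", 5), seq(0L, 40000L, 10000L),
                seq(1000L, 41000L, 10000L), signal = 1)
  pvals <- vapply(1:150, function(i) {
    reg <- GRanges("chrT", IRanges(sample.int(L - 800L, 2), width = 300))
    chip_overlap_test(chip, reg, c(chrT = L), n_perm = 100,
                      seed = 1000 + i)$p_value
  }, numeric(1))
  for (alpha in c(0.05, 0.1, 0.25)) {
    # P(p <= alpha) <= alpha, allowing binomial noise over 150 draws
    tol <- 1.96 * sqrt(alpha * (1 - alpha) / 150)
    expect_lte(mean(pvals <= alpha), alpha + tol)
  }
})
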