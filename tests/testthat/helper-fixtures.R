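# Shared fixtures: all built in code, nothing read from disk.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# random per-sample peak sets on one chromosome, 0-based half-open inputs
random_peak_sets <- function(n_samples, chrom_len, max_peaks = 8,
                             chrom = "chrT") {
  lapply(seq_len(n_samples), function(s) {
    np <- sample.int(max_peaks, 1)
    s0 <- sort(sample.int(chrom_len - 50, np)) - 1L
    w <- sample(5:200, np, replace = TRUE)
    e0 <- pmin(s0 + w, chrom_len)
    peaks(rep(chrom, np), s0, e0, signal = runif(np, 1, 10))
  })
}

# brute-force per-base consensus oracle (single chromosome)
oracle_consensus <- function(peak_sets, min_support, chrom_len) {
  n <- length(peak_sets)
  k <- ceiling(min_support * n)
  counts <- integer(chrom_len)
  for (p in peak_sets) {
    covered <- logical(chrom_len)
    for (i in seq_along(p)) {
      covered[start(p)[i]:min(end(p)[i], chrom_len)] <- TRUE
    }
    counts <- counts + covered
  }
  sup <- counts >= k
  r <- rle(sup)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# one-region AccessibilityMatrix from the generator's emitted truth signal
acc_from_cohort <- function(cohort) {
  gr <- GRanges("chrP", IRanges(1, cohort$config$promoter_peak_width))
  m <- matrix(cohort$accessibility, nrow = 1,
              dimnames = list(NULL, names(cohort$accessibility)))
  accessibility_matrix(gr, m, "log2")
}

# a fast cohort configuration for replicate-heavy statistical tests: the
# screen consumes only the expression / accessibility matrices, so peak
# geometry is scaled down without touching effect sizes or noise
fast_config <- function(n_samples = 41, ...) {
  cohort_config(n_samples = n_samples, n_genes = 23,
                n_background_peaks = 0, ...)
}

# exhaustive per-window PWM re-scorer, independent of scan_pwm internals
oracle_scan <- function(sequence, pwm, threshold) {
  L <- ncol(pwm$matrix)
  n <- nchar(sequence)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- list()
  if (L > n) return(data.frame())
  for (s in seq_len(n - L + 1)) {
    win <- substr(sequence, s, s + L - 1)
    bases <- strsplit(win, "")[[1]]
    if (any(bases == "N")) next
    fwd <- sum(vapply(seq_len(L), function(j) {
      log2(pwm$matrix[bases[j], j] / pwm$background[bases[j]])
    }, numeric(1)))
    rcb <- rev(unname(comp[bases]))
    rev_sc <- sum(vapply(seq_len(L), function(j) {
      log2(pwm$matrix[rcb[j], j] / pwm$background[rcb[j]])
    }, numeric(1)))
    if (fwd >= threshold) out[[length(out) + 1]] <-
      data.frame(start = s, strand = "+", score = fwd)
    if (rev_sc >= threshold) out[[length(out) + 1]] <-
      data.frame(start = s, strand = "-", score = rev_sc)
  }
  if (!length(out)) return(data.frame())
  do.call(rbind, out)
}

random_pwm <- function(L) {
  counts <- matrix(rpois(4 * L, 3) + 1, nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm_from_counts(counts, pseudocount = 0.5)
}
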