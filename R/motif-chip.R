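# PWM motif scanning and permutation-based ChIP-seq overlap testing: the
# physical-binding validation layer behind a correlation-screen candidate.

#' Build a position weight matrix from base counts
#'
#' `p(b, j) = (count(b, j) + pseudocount) / (colsum(j) + 4 * pseudocount)`.
#'
#' @param counts 4 x L non-negative matrix, rows A, C, G, T.
#' @param pseudocount Added per cell; default 0.25 spreads one pseudo-
#'   observation over the four bases.
#' @param background Length-4 base frequencies summing to 1.
#' @param name Motif name.
#' @return A `pwm` object: `name`, `matrix` (4 x L column-stochastic),
#'   `background`, `pseudocount`.
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.25,
                            background = rep(0.25, 4), name = "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("counts must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (ncol(counts) < 1) stop("motif must have length >= 1")
  cs <- colSums(counts)
  if (any(cs + 4 * pseudocount == 0)) {
    stop("all-zero column with zero pseudocount")
  }
  if (abs(sum(background) - 1) > 1e-9 || any(background <= 0)) {
    stop("background must be positive and sum to 1")
  }
  m <- sweep(counts + pseudocount, 2, cs + 4 * pseudocount, "/")
  rownames(m) <- c("A", "C", "G", "T")
  structure(list(name = name, matrix = m,
                 background = setNames(background, c("A", "C", "G", "T")),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' Consensus sequence of a PWM (argmax base per column)
#'
#' Ties resolve to the alphabetically first base.
#'
#' @param pwm A `pwm` object.
#' @return Character consensus string.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$matrix)[apply(pwm$matrix, 2, which.max)], collapse = "")
}

#' Maximum achievable log2-odds score of a PWM
#'
#' @param pwm A `pwm` object.
#' @return Bits.
#' @export
pwm_max_score <- function(pwm) {
  lo <- log2(pwm$matrix / pwm$background)
  sum(apply(lo, 2, max))
}

#' Read JASPAR-style PFM text
#'
#' Accepts the JASPAR 2020 format: a `>ID name` header followed by four
#' lines `A [ 4 19 0 ... ]` (brackets optional).
#'
#' @param path File path.
#' @param ... Passed to [pwm_from_counts()].
#' @return A list of `pwm` objects, one per record.
#' @export
read_jaspar_pfm <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no '>' header found in PFM file")
  out <- list()
  for (i in seq_along(hdr)) {
    from <- hdr[i] + 1
    to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(lines)
    block <- lines[from:to]
    if (length(block) < 4) stop("PFM record needs 4 base rows")
    nm <- sub("^>\\s*", "", lines[hdr[i]])
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("[][]", " ", l)
      v <- strsplit(trimws(l), "\\s+")[[1]]
      base <- v[1]
      list(base = base, counts = as.numeric(v[-1]))
    })
    bases <- vapply(rows, `[[`, "", "base")
    if (!setequal(bases, c("A", "C", "G", "T"))) {
      stop("PFM rows must be labelled A, C, G, T")
    }
    counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
    rownames(counts) <- bases
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
    out[[i]] <- pwm_from_counts(counts, name = nm, ...)
  }
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

seq_to_index <- function(sequence) {
  v <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(v, c("A", "C", "G", "T"))  # N and anything else -> NA
  if (any(is.na(idx) & !v %in% "N")) {
    stop("sequence must be over the alphabet {A, C, G, T, N}")
  }
  idx
}

#' Scan a sequence with a PWM
#'
#' Scores every window of motif length with the summed log2 odds
#' `sum_j log2(p(base_j, j) / background(base_j))`.  Windows containing N
#' are skipped.  The minus strand scans the reverse complement with
#' coordinates mapped back to the forward strand.  Hits with score >=
#' `threshold_bits` are returned sorted by position, `+` before `-`.
#'
#' @param sequence Character string over A/C/G/T/N.
#' @param pwm A `pwm` object.
#' @param threshold_bits Minimum reported score; default 80% of the PWM's
#'   maximal achievable score.
#' @param strands `"both"`, `"+"` or `"-"`.
#' @return A data.frame of motif hits: `start`, `end` (1-based inclusive),
#'   `strand`, `score` (bits), `match` (forward-strand sequence of the
#'   window).
#' @export
scan_pwm <- function(sequence, pwm, threshold_bits = 0.8 * pwm_max_score(pwm),
                     strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  L <- ncol(pwm$matrix)
  n <- nchar(sequence)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      match = character(), stringsAsFactors = FALSE)
  if (L > n) return(empty)
  idx <- seq_to_index(sequence)
  lo_fwd <- log2(pwm$matrix / pwm$background)
  # a minus-strand hit at forward window [s, s+L) is a match of the PWM on
  # the reverse complement, i.e. the reverse-complemented log-odds matrix
  # applied to the forward bases
  lo_rev <- lo_fwd[4:1, L:1, drop = FALSE]
  nw <- n - L + 1L
  score_with <- function(lo) {
    sc <- numeric(nw)
    ok <- rep(TRUE, nw)
    for (j in seq_len(L)) {
      b <- idx[j:(j + nw - 1L)]
      miss <- is.na(b)
      ok <- ok & !miss
      b[miss] <- 1L
      sc <- sc + lo[cbind(b, j)]
    }
    sc[!ok] <- -Inf
    sc
  }
  res <- empty
  wins <- seq_len(nw)
  starts <- wins
  ends <- wins + L - 1L
  matches <- substring(sequence, starts, ends)
  if (strands %in% c("both", "+")) {
    sc <- score_with(lo_fwd)
    keep <- is.finite(sc) & sc >= threshold_bits
    res <- rbind(res, data.frame(start = starts[keep], end = ends[keep],
                                 strand = rep("+", sum(keep)),
                                 score = sc[keep], match = matches[keep],
                                 stringsAsFactors = FALSE))
  }
  if (strands %in% c("both", "-")) {
    sc <- score_with(lo_rev)
    keep <- is.finite(sc) & sc >= threshold_bits
    res <- rbind(res, data.frame(start = starts[keep], end = ends[keep],
                                 strand = rep("-", sum(keep)),
                                 score = sc[keep], match = matches[keep],
                                 stringsAsFactors = FALSE))
  }
  res[order(res$start, res$strand), , drop = FALSE]
}

#' Permutation test for ChIP-peak overlap with candidate regions
#'
#' The observed statistic is the number of regions overlapping at least
#' one ChIP peak.  The null re-places each region uniformly
#' (width-preserving) on its own chromosome, independently per
#' permutation; `p = (1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param chip_peaks A peak `GRanges`.
#' @param regions A `GRanges` of candidate regions.
#' @param chrom_sizes Named vector of chromosome lengths covering every
#'   region's chromosome.
#' @param n_perm Number of permutations, >= 100.
#' @param seed Integer RNG seed.
#' @return A list: `observed`, `p_value`, `n_perm`, `null` (the null
#'   counts).
#' @export
chip_overlap_test <- function(chip_peaks, regions, chrom_sizes,
                              n_perm = 1000, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!length(regions)) stop("no regions supplied")
  chroms <- as.character(seqnames(regions))
  if (any(!chroms %in% names(chrom_sizes))) {
    stop("chrom_sizes must cover every region's chromosome")
  }
  w <- width(regions)
  L <- as.integer(chrom_sizes[chroms])
  if (any(w > L)) stop("region wider than its chromosome")
  observed <- sum(countOverlaps(regions, chip_peaks, ignore.strand = TRUE) > 0)
  set.seed(seed)
  nr <- length(regions)
  # draw all permuted starts at once: start1 uniform on [1, L - w + 1]
  starts <- matrix(floor(runif(n_perm * nr) * rep(L - w + 1L, n_perm)) + 1L,
                   nrow = nr)
  perm_gr <- GRanges(rep(chroms, n_perm),
                     IRanges(as.vector(starts), width = rep(w, n_perm)))
  hit <- countOverlaps(perm_gr, chip_peaks, ignore.strand = TRUE) > 0
  null_counts <- as.integer(rowsum(as.integer(hit),
                                   rep(seq_len(n_perm), each = nr)))
  p <- (1 + sum(null_counts >= observed)) / (n_perm + 1)
  list(observed = observed, p_value = p, n_perm = n_perm, null = null_counts)
}

#' Write motif hits as BED6 plus an exact-score TSV
#'
#' BED score column carries bits x 100 (capped at 1000); exact scores go
#' in a side TSV.
#'
#' @param hits Data.frame from [scan_pwm()].
#' @param chrom Chromosome name for the scanned sequence.
#' @param offset 0-based genomic position of sequence base 1.
#' @param path BED output path; TSV written with extension `.tsv`.
#' @return `path`, invisibly.
#' @export
write_motif_hits <- function(hits, chrom, offset = 0L, path) {
  df <- data.frame(chrom, offset + hits$start - 1L, offset + hits$end,
                   hits$match, pmin(round(hits$score * 100), 1000),
                   hits$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(cbind(hits, chrom = chrom),
              paste0(sub("\\.bed$", "", path), ".tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
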