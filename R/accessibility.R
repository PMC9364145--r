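#' Accessibility matrix container
#'
#' A light S3 container pairing consensus regions with a regions x samples
#' signal matrix.  Row names of `values` are the display coordinates of
#' `regions`; column names are the sample IDs.
#'
#' @param regions A `GRanges` of (non-overlapping) consensus regions.
#' @param values Numeric matrix, `length(regions)` x `n_samples`.
#' @param normalization Tag describing the scale of `values`.
#' @return An `AccessibilityMatrix` object.
#' @export
accessibility_matrix <- function(regions, values, normalization = "raw") {
  stopifnot(is.matrix(values), nrow(values) == length(regions))
  if (any(!is.finite(values))) stop("accessibility values must be finite")
  rownames(values) <- format_region(regions)
  structure(list(regions = regions, samples = colnames(values),
                 values = values, normalization = normalization),
            class = "AccessibilityMatrix")
}

#' @export
print.AccessibilityMatrix <- function(x, ...) {
  cat(sprintf("AccessibilityMatrix: %d regions x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$normalization))
  print(head(x$values, 3))
  invisible(x)
}

#' Quantify per-sample accessibility over consensus regions
#'
#' The accessibility of a region in a sample is the sum, over that sample's
#' peaks, of peak signal weighted by the fraction of the peak overlapping
#' the region: `signal * overlap_bp / peak_width`.  Samples with no
#' overlapping peak score 0.  This statistic is additive under peak
#' splitting and robust to boundary jitter.
#'
#' @param regions Non-overlapping `GRanges` of consensus regions.
#' @param peak_sets Named list of peak `GRanges`, one per sample.
#' @return A raw-scale `AccessibilityMatrix`.
#' @export
quantify_accessibility <- function(regions, peak_sets) {
  if (length(regions) > 1 &&
      !isDisjoint(granges(regions), ignore.strand = TRUE)) {
    stop("consensus regions must be non-overlapping")
  }
  if (is.null(names(peak_sets))) {
    names(peak_sets) <- sprintf("sample_%02d", seq_along(peak_sets))
  }
  vals <- matrix(0, nrow = length(regions), ncol = length(peak_sets),
                 dimnames = list(NULL, names(peak_sets)))
  for (j in seq_along(peak_sets)) {
    p <- peak_sets[[j]]
    if (!length(p)) next
    hits <- findOverlaps(regions, p, ignore.strand = TRUE)
    if (!length(hits)) next
    ov <- pintersect(granges(regions)[queryHits(hits)],
                     granges(p)[subjectHits(hits)], ignore.strand = TRUE)
    w <- width(ov) / width(p)[subjectHits(hits)]
    contrib <- mcols(p)$signal[subjectHits(hits)] * w
    vals[, j] <- as.numeric(tapply(contrib, factor(queryHits(hits),
                                                   levels = seq_along(regions)),
                                   sum, default = 0))
  }
  accessibility_matrix(regions, vals, "raw")
}

#' Normalize an accessibility matrix
#'
#' `cpm_log2` rescales each sample column to a total signal of 1e6 and then
#' applies `log2(x + pseudocount)`, removing per-sample depth factors.
#' All-zero columns are left at 0 with a warning.  `none` is the identity.
#'
#' When the matrix covers only a handful of target regions, the column
#' totals are a poor depth estimate; `size_factors` lets callers supply
#' per-sample library totals (e.g. the summed signal of each sample's full
#' peak set) to scale by instead.
#'
#' @param x An `AccessibilityMatrix` with raw (non-negative) values.
#' @param method `"cpm_log2"` or `"none"`.
#' @param pseudocount Added before the log; default 1.
#' @param size_factors Optional named per-sample totals used in place of
#'   the matrix column sums for the scaling step.
#' @return A normalized `AccessibilityMatrix`.
#' @export
normalize_accessibility <- function(x, method = c("cpm_log2", "none"),
                                    pseudocount = 1, size_factors = NULL) {
  method <- match.arg(method)
  if (method == "none") return(x)
  v <- x$values
  if (any(v < 0)) stop("cpm_log2 requires non-negative raw values")
  cs <- if (is.null(size_factors)) colSums(v) else {
    if (is.null(names(size_factors))) size_factors else
      size_factors[colnames(v)]
  }
  zero <- cs == 0
  if (any(zero)) {
    warning("all-zero sample column(s) left at 0: ",
            paste(colnames(v)[zero], collapse = ", "))
    cs[zero] <- 1
  }
  v <- sweep(v, 2, cs, "/") * 1e6
  v[, zero] <- 0
  out <- log2(v + pseudocount)
  out[, zero] <- 0
  accessibility_matrix(x$regions, out, "cpm_log2")
}

#' Write an accessibility matrix as TSV
#'
#' Regions become row keys in display coordinates ("chrom:start-end").
#'
#' @param x An `AccessibilityMatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accessibility <- function(x, path) {
  df <- data.frame(region = rownames(x$values), x$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an accessibility matrix TSV
#'
#' @param path TSV written by [write_accessibility()].
#' @return An `AccessibilityMatrix` (regions reconstructed from row keys;
#'   normalization tag `"file"`).
#' @export
read_accessibility <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  keys <- df$region
  m <- as.matrix(df[, -1, drop = FALSE])
  parts <- regmatches(keys, regexec("^(.+):(\\d+)-(\\d+)$", keys))
  gr <- GRanges(vapply(parts, `[`, "", 2),
                IRanges(as.integer(vapply(parts, `[`, "", 3)),
                        as.integer(vapply(parts, `[`, "", 4))))
  accessibility_matrix(gr, m, "file")
}
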