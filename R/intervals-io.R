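#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames seqlevels seqlevels<-
#' @importFrom stats rnorm runif setNames
#' @importFrom utils read.table write.table head
NULL

# Coordinate conventions
# ----------------------
# On disk, BED-family formats are 0-based half-open.  In memory every
# interval is a GRanges and therefore 1-based closed, the Bioconductor
# convention; the two agree on the displayed coordinates, e.g. the BED row
# "chr9 5449462 5449962" is held as chr9:5449463-5449962 and displayed that
# way.  All user-facing coordinates in this package are 1-based inclusive.

#' Create a peak GRanges
#'
#' Builds the internal peak container: a `GRanges` with metadata columns
#' `name`, `signal` and `summit` (summit offset in bp from the peak start,
#' `NA` when unknown).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open (BED convention).
#' @param name Peak names (recycled).
#' @param signal Non-negative signal values (recycled).
#' @param summit Integer summit offsets from peak start, or `NA`.
#' @param strand Strand characters; defaults to `"*"`.
#' @return A `GRanges` with the peak metadata columns.
#' @export
peaks <- function(chrom, start, end, name = ".", signal = 0, summit = NA_integer_,
                  strand = "*") {
  if (any(end <= start)) {
    stop("peak intervals must satisfy end > start (0-based half-open)")
  }
  if (any(start < 0)) stop("peak start must be >= 0")
  sig <- rep_len(as.numeric(signal), length(chrom))
  if (any(sig < 0)) stop("peak signal must be non-negative")
  smt <- rep_len(as.integer(summit), length(chrom))
  w <- end - start
  bad <- !is.na(smt) & (smt < 0 | smt >= w)
  if (any(bad)) stop("summit offset must lie within the peak: [0, width)")
  gr <- GRanges(chrom, IRanges(start + 1L, end), strand = rep_len(strand, length(chrom)))
  mcols(gr)$name <- rep_len(as.character(name), length(gr))
  mcols(gr)$signal <- sig
  mcols(gr)$summit <- smt
  gr
}

#' Read peaks from a BED-family file
#'
#' Parses BED3, BED6 or ENCODE narrowPeak (10 columns).  Coordinates are
#' 0-based half-open on disk and converted to the in-memory 1-based closed
#' `GRanges` representation.  `track`, `browser` and `#` comment lines are
#' skipped.  For narrowPeak, column 10 is the summit offset; `-1` means the
#' summit is unknown and is stored as `NA`.
#'
#' @param path File path.
#' @param dialect One of `"bed3"`, `"bed6"`, `"narrowPeak"`.
#' @return A peak `GRanges` (see [peaks()]).
#' @export
read_peaks <- function(path, dialect = c("narrowPeak", "bed6", "bed3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  ncol_needed <- c(bed3 = 3L, bed6 = 6L, narrowPeak = 10L)[[dialect]]
  if (length(lines) == 0L) {
    return(peaks(character(), integer(), integer())[0])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < ncol_needed)) {
    i <- which(nf < ncol_needed)[1]
    stop(sprintf("line %d: expected >= %d tab-separated fields for %s, got %d",
                 lineno[i], ncol_needed, dialect, nf[i]))
  }
  col <- function(j) vapply(fields, `[[`, character(1), j)
  start <- suppressWarnings(as.integer(col(2)))
  end <- suppressWarnings(as.integer(col(3)))
  bad <- is.na(start) | is.na(end) | end <= start | start < 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("line %d: malformed interval (need integer 0 <= start < end)",
                 lineno[i]))
  }
  nm <- if (dialect == "bed3") "." else col(4)
  strand <- if (dialect == "bed3") "*" else {
    s <- col(6)
    s[!s %in% c("+", "-")] <- "*"
    s
  }
  signal <- if (dialect == "narrowPeak") {
    suppressWarnings(as.numeric(col(7)))
  } else if (dialect == "bed6") {
    suppressWarnings(as.numeric(col(5)))
  } else {
    rep(0, length(start))
  }
  if (any(is.na(signal))) {
    stop(sprintf("line %d: non-numeric signal", lineno[which(is.na(signal))[1]]))
  }
  summit <- if (dialect == "narrowPeak") {
    s <- suppressWarnings(as.integer(col(10)))
    s[!is.na(s) & s == -1L] <- NA_integer_
    s
  } else {
    rep(NA_integer_, length(start))
  }
  peaks(col(1), start, end, name = nm, signal = signal, summit = summit,
        strand = strand)
}

#' Write peaks to a BED-family file
#'
#' Inverse of [read_peaks()]: writes 0-based half-open coordinates.  For
#' BED6 the score column is the signal capped at 1000 (BED spec); for
#' narrowPeak the signal goes in column 7 uncapped and absent summits are
#' written as `-1`.
#'
#' @param x A peak `GRanges`.
#' @param path Output path.
#' @param dialect One of `"bed3"`, `"bed6"`, `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(x, path, dialect = c("narrowPeak", "bed6", "bed3")) {
  dialect <- match.arg(dialect)
  chrom <- as.character(seqnames(x))
  s0 <- start(x) - 1L
  e0 <- end(x)
  nm <- if (!is.null(mcols(x)$name)) mcols(x)$name else rep(".", length(x))
  sig <- if (!is.null(mcols(x)$signal)) mcols(x)$signal else rep(0, length(x))
  str <- as.character(strand(x))
  str[str == "*"] <- "."
  df <- switch(dialect,
    bed3 = data.frame(chrom, s0, e0),
    bed6 = data.frame(chrom, s0, e0, nm, pmin(round(sig), 1000), str),
    narrowPeak = {
      smt <- if (!is.null(mcols(x)$summit)) mcols(x)$summit else rep(NA_integer_, length(x))
      smt[is.na(smt)] <- -1L
      data.frame(chrom, s0, e0, nm, pmin(round(sig), 1000), str,
                 sig, -1, -1, smt)
    })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Format regions as 1-based display coordinates
#'
#' @param x A `GRanges`.
#' @return Character vector like `"chr9:5449463-5449962"`.
#' @export
format_region <- function(x) {
  sprintf("%s:%d-%d", as.character(seqnames(x)), start(x), end(x))
}

#' Read a gene model table
#'
#' Gene models are supplied as BED6 with the TSS as a 1 bp interval:
#' columns chrom, tss, tss+1, gene, score, strand (0-based on disk).
#' Strand is mandatory.
#'
#' @param path BED6 file path.
#' @return A data.frame with columns `gene`, `chrom`, `tss` (1-based
#'   position of the transcription start site) and `strand`.
#' @export
read_gene_models <- function(path) {
  p <- read_peaks(path, "bed6")
  str <- as.character(strand(p))
  if (any(!str %in% c("+", "-"))) {
    stop("gene models require an explicit +/- strand")
  }
  data.frame(gene = mcols(p)$name, chrom = as.character(seqnames(p)),
             tss = start(p), strand = str, stringsAsFactors = FALSE)
}

#' Write a gene model table as BED6
#'
#' @param genes Data.frame as returned by [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  df <- data.frame(genes$chrom, genes$tss - 1L, genes$tss, genes$gene, 0,
                   genes$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Strand-aware promoter windows for gene models
#'
#' The promoter of a plus-strand gene with TSS `t` covers `upstream` bp
#' before and `downstream` bp after the TSS; minus-strand promoters are the
#' mirror image.
#'
#' @param genes Gene model data.frame (`gene`, `chrom`, `tss`, `strand`).
#' @param upstream,downstream Non-negative window extents in bp.
#' @return A named `GRanges` of promoter windows.
#' @export
promoter_windows <- function(genes, upstream = 2000, downstream = 500) {
  if (upstream < 0 || downstream < 0) stop("window extents must be >= 0")
  tssr <- GRanges(genes$chrom, IRanges(genes$tss, width = 1L),
                  strand = genes$strand)
  pr <- promoters(tssr, upstream = upstream, downstream = downstream)
  pr <- restrict(pr, start = 1L)
  names(pr) <- genes$gene
  mcols(pr)$gene <- genes$gene
  mcols(pr)$tss <- genes$tss
  pr
}

#' Call cohort-consensus open-chromatin regions
#'
#' A base is *supported* when covered by peaks from at least
#' `ceiling(min_support * n_samples)` distinct samples (duplicate peaks
#' within one sample never add support).  Maximal runs of supported bases
#' form the raw consensus regions.  When `fixed_width` is given, each run
#' is replaced by a window of that width centred on the run midpoint
#' (floor), trimmed at chromosome ends when `chrom_sizes` is supplied.
#'
#' @param peak_sets A list of peak `GRanges`, one element per sample.
#' @param min_support Fraction of samples in (0, 1] that must cover a base.
#' @param fixed_width Optional standardized region width in bp.
#' @param chrom_sizes Optional named vector of chromosome lengths used to
#'   trim fixed-width windows.
#' @return A `GRanges` of consensus regions with a `support` metadata
#'   column: the number of samples having >= 1 bp overlap with the final
#'   region.
#' @export
consensus_regions <- function(peak_sets, min_support = 0.9, fixed_width = NULL,
                              chrom_sizes = NULL) {
  if (!is.list(peak_sets) || length(peak_sets) < 1) {
    stop("peak_sets must be a non-empty list of GRanges")
  }
  if (!is.numeric(min_support) || length(min_support) != 1 ||
      min_support <= 0 || min_support > 1) {
    stop("min_support must lie in (0, 1]")
  }
  n <- length(peak_sets)
  k <- ceiling(min_support * n)
  lvls <- sort(unique(unlist(lapply(peak_sets, function(g) as.character(seqnames(g))))))
  if (length(lvls) == 0L) {
    out <- GRanges()
    mcols(out)$support <- integer()
    return(out)
  }
  maxend <- setNames(integer(length(lvls)), lvls)
  for (g in peak_sets) {
    if (!length(g)) next
    me <- tapply(end(g), as.character(seqnames(g)), max)
    maxend[names(me)] <- pmax(maxend[names(me)], as.integer(me))
  }
  cov <- NULL
  for (g in peak_sets) {
    g <- reduce(granges(g), ignore.strand = TRUE)  # distinct-sample counting
    seqlevels(g) <- lvls
    ci <- coverage(g, width = maxend)
    cov <- if (is.null(cov)) ci else cov + ci
  }
  sup <- slice(cov, lower = k, rangesOnly = TRUE)
  out <- GRanges(rep(names(sup), lengths(sup)), unlist(sup, use.names = FALSE))
  out <- sort(out)
  if (!is.null(fixed_width)) {
    fixed_width <- as.integer(fixed_width)
    if (fixed_width < 1) stop("fixed_width must be >= 1")
    # 0-based midpoint floor((s0 + e0) / 2); window [mid - w/2, mid + w - w/2)
    s0 <- start(out) - 1L
    e0 <- end(out)
    mid <- (s0 + e0) %/% 2L
    ns0 <- mid - fixed_width %/% 2L
    ne0 <- ns0 + fixed_width
    out2 <- GRanges(seqnames(out), IRanges(pmax(ns0, 0L) + 1L, ne0))
    if (!is.null(chrom_sizes)) {
      lens <- chrom_sizes[as.character(seqnames(out2))]
      out2 <- GRanges(seqnames(out2),
                      IRanges(start(out2), pmin(end(out2), as.integer(lens))))
    }
    out <- out2
  }
  support <- integer(length(out))
  for (g in peak_sets) {
    support <- support + as.integer(countOverlaps(out, g, ignore.strand = TRUE) > 0)
  }
  mcols(out)$support <- support
  out
}

#' Assign regions to gene promoters
#'
#' A region is assigned to a gene when it overlaps that gene's strand-aware
#' promoter window by at least 1 bp.  When several promoters overlap, the
#' gene whose TSS is nearest the region midpoint wins; exact distance ties
#' go to the lexicographically smallest symbol.  Unmapped regions are kept
#' and flagged, never dropped.
#'
#' @param regions A `GRanges` of regions.
#' @param genes Gene model data.frame.
#' @param upstream,downstream Promoter window extents in bp.
#' @return A data.frame with one row per region: `region` (display
#'   coordinates), `gene` (`NA` when unmapped) and `distance` (bp from the
#'   region midpoint to the TSS).
#' @export
assign_promoters <- function(regions, genes, upstream = 2000, downstream = 500) {
  pr <- promoter_windows(genes, upstream, downstream)
  hits <- findOverlaps(regions, pr, ignore.strand = TRUE)
  mid <- (start(regions) + end(regions)) %/% 2L
  out <- data.frame(region = format_region(regions),
                    gene = NA_character_, distance = NA_integer_,
                    stringsAsFactors = FALSE)
  if (length(hits)) {
    d <- abs(mid[queryHits(hits)] - mcols(pr)$tss[subjectHits(hits)])
    g <- mcols(pr)$gene[subjectHits(hits)]
    ord <- order(queryHits(hits), d, g)
    first <- !duplicated(queryHits(hits)[ord])
    qi <- queryHits(hits)[ord][first]
    out$gene[qi] <- g[ord][first]
    out$distance[qi] <- d[ord][first]
  }
  out
}

#' Classify regions by genomic feature
#'
#' Each region receives exactly one class, with priority
#' promoter > exon > intron > intergenic.
#'
#' @param regions A `GRanges`.
#' @param genes Gene model data.frame (defines promoter windows).
#' @param exons,introns Optional `GRanges` of exonic / intronic intervals.
#' @param upstream,downstream Promoter window extents in bp.
#' @return A list with `classes` (character vector, one per region) and
#'   `counts` (named table over the four classes; sums to
#'   `length(regions)`).
#' @export
annotate_features <- function(regions, genes, exons = NULL, introns = NULL,
                              upstream = 2000, downstream = 500) {
  cls <- rep("intergenic", length(regions))
  pr <- promoter_windows(genes, upstream, downstream)
  if (!is.null(introns) && length(introns)) {
    cls[countOverlaps(regions, introns, ignore.strand = TRUE) > 0] <- "intron"
  }
  if (!is.null(exons) && length(exons)) {
    cls[countOverlaps(regions, exons, ignore.strand = TRUE) > 0] <- "exon"
  }
  cls[countOverlaps(regions, pr, ignore.strand = TRUE) > 0] <- "promoter"
  lv <- c("promoter", "exon", "intron", "intergenic")
  list(classes = cls, counts = table(factor(cls, levels = lv)))
}

#' Write consensus regions as BED6 plus an exact-support TSV
#'
#' The BED score column holds the support count capped at 1000; exact
#' support goes in the side TSV.
#'
#' @param regions Consensus `GRanges` with a `support` column.
#' @param path BED6 output path; the TSV is written next to it with
#'   extension `.support.tsv`.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(regions, path) {
  sup <- mcols(regions)$support
  df <- data.frame(as.character(seqnames(regions)), start(regions) - 1L,
                   end(regions), format_region(regions), pmin(sup, 1000), ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  tsv <- sub("\\.bed$", "", path)
  tsv <- paste0(tsv, ".support.tsv")
  write.table(data.frame(region = format_region(regions), support = sup),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
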