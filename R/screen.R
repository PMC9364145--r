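# The correlation screen: inflammatory TF panel, TF expression vs
# target-promoter accessibility, BH false-discovery control, deterministic
# candidate ranking.

#' Build the curated inflammatory transcription factor panel
#'
#' The panel unions the three TF families central to inflammatory
#' signalling: NF-kB (NFKB1, NFKB2, RELA, RELB, REL), the interferon
#' regulatory factors IRF1-IRF9, and the STATs (STAT1-4, STAT5A, STAT5B,
#' STAT6) - 21 symbols in total.
#'
#' @return A data.frame with columns `symbol` and `family`
#'   (`"NF-kB"`, `"IRF"`, `"STAT"`) and attribute `source =
#'   "inflammatory_panel"`.
#' @export
build_inflammatory_panel <- function() {
  nfkb <- c("NFKB1", "NFKB2", "RELA", "RELB", "REL")
  irf <- paste0("IRF", 1:9)
  stat <- c("STAT1", "STAT2", "STAT3", "STAT4", "STAT5A", "STAT5B", "STAT6")
  panel <- data.frame(
    symbol = c(nfkb, irf, stat),
    family = rep(c("NF-kB", "IRF", "STAT"),
                 times = c(length(nfkb), length(irf), length(stat))),
    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(panel$symbol))
  attr(panel, "source") <- "inflammatory_panel"
  panel
}

#' Screen configuration
#'
#' @param method Correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @param p_threshold Raw p-value gate, default 0.05.
#' @param r_threshold Correlation gate used by the dual filter, default
#'   0.4.
#' @param require_all_regions Must a candidate pass the p gate in every
#'   promoter region (default) or in at least one?
#' @param top_k Number of top candidates highlighted in reports.
#' @return A `screen_config` list.
#' @export
screen_config <- function(method = c("pearson", "spearman"),
                          p_threshold = 0.05, r_threshold = 0.4,
                          require_all_regions = TRUE, top_k = 5) {
  method <- match.arg(method)
  stopifnot(p_threshold > 0, p_threshold <= 1,
            r_threshold >= -1, r_threshold <= 1, top_k >= 1)
  structure(list(method = method, p_threshold = p_threshold,
                 r_threshold = r_threshold,
                 require_all_regions = isTRUE(require_all_regions),
                 top_k = as.integer(top_k)),
            class = "screen_config")
}

#' Correlate two sample-aligned vectors
#'
#' Pearson is the standard product-moment coefficient; Spearman is Pearson
#' on average ranks.  The two-sided p-value uses the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#' Zero-variance input yields `r = NA` with `ok = FALSE`; such records are
#' excluded downstream rather than erroring the screen.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, finite.
#' @param feature_a,feature_b Identifiers carried into the record.
#' @param method `"pearson"` or `"spearman"`.
#' @return A one-row data.frame (a correlation record): `feature_a`,
#'   `feature_b`, `r`, `n`, `p`, `q` (`NA` until FDR adjustment),
#'   `method`, `ok`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      feature_a = "x", feature_b = "y") {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("correlation requires n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite")
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  rec <- data.frame(feature_a = feature_a, feature_b = feature_b,
                    r = NA_real_, n = n, p = NA_real_, q = NA_real_,
                    method = method, ok = FALSE, stringsAsFactors = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(rec)
  r <- stats::cor(x, y)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  rec$r <- r
  rec$p <- p
  rec$ok <- TRUE
  rec
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q(i) = min_{j >= i} p(j) * m / j` over the ascending-sorted p-values,
#' capped at 1 and mapped back to the input order.  `NA` p-values (from
#' degenerate correlation records) propagate as `NA`.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  keep <- !is.na(p)
  pv <- p[keep]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pv)
  q <- rep(NA_real_, length(p))
  if (m > 0) {
    o <- order(pv)
    qs <- pmin(1, rev(cummin(rev(pv[o] * m / seq_len(m)))))
    qq <- numeric(m)
    qq[o] <- qs
    q[keep] <- qq
  }
  q
}

#' Read an expression matrix TSV (genes x samples)
#'
#' First column holds gene symbols; remaining columns are samples.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write an expression matrix TSV
#'
#' @param expr Genes x samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Screen a TF panel against target-promoter accessibility
#'
#' For every (TF, region) pair the TF's expression is correlated with the
#' region's accessibility across the shared samples; q-values are BH
#' adjusted over the whole record set.  Each TF is additionally correlated
#' with the target gene's expression (`r_target`).  A TF is a *candidate*
#' when its raw p beats `config$p_threshold` in every region
#' (`require_all_regions`) or in at least one.  Ranking is the
#' deterministic 4-level key: mean per-region r (descending), `r_target`
#' (descending), minimum region p (ascending), symbol.
#'
#' @param expr Genes x samples expression matrix (log2 scale).
#' @param acc An `AccessibilityMatrix` whose samples appear in
#'   `colnames(expr)`.
#' @param panel TF panel data.frame (`symbol`, optional `family`), or a
#'   character vector of symbols.
#' @param target_gene Target gene symbol; must be a row of `expr`.
#' @param config A [screen_config()].
#' @return A list with `records` (all per-(TF, region) correlation
#'   records), `summary` (one ranked row per TF: `tf`, `family`,
#'   `r_region`, `r_target`, `p_min`, `q_min`, `candidate`, `rank`), and
#'   `missing` (panel symbols absent from `expr`).
#' @export
screen_tfs <- function(expr, acc, panel, target_gene,
                       config = screen_config()) {
  if (is.character(panel)) {
    panel <- data.frame(symbol = panel, family = NA_character_,
                        stringsAsFactors = FALSE)
  }
  if (!target_gene %in% rownames(expr)) {
    stop("target gene not found in expression matrix: ", target_gene)
  }
  shared <- intersect(colnames(expr), colnames(acc$values))
  if (length(shared) < 3) stop("expression and accessibility share < 3 samples")
  expr <- expr[, shared, drop = FALSE]
  av <- acc$values[, shared, drop = FALSE]
  missing <- setdiff(panel$symbol, rownames(expr))
  tfs <- setdiff(intersect(panel$symbol, rownames(expr)), target_gene)
  if (!length(tfs)) stop("no panel member present in the expression matrix")
  regions <- rownames(av)
  tgt <- expr[target_gene, ]

  recs <- vector("list", length(tfs) * length(regions))
  k <- 0L
  tsum <- data.frame(tf = tfs,
                     family = panel$family[match(tfs, panel$symbol)],
                     r_region = NA_real_, r_target = NA_real_,
                     p_min = NA_real_, q_min = NA_real_,
                     candidate = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(tfs)) {
    xv <- expr[tfs[i], ]
    for (j in seq_along(regions)) {
      k <- k + 1L
      recs[[k]] <- correlate(xv, av[j, ], method = config$method,
                             feature_a = tfs[i], feature_b = regions[j])
    }
  }
  records <- do.call(rbind, recs)
  records$q <- bh_fdr(records$p)

  for (i in seq_along(tfs)) {
    rr <- records[records$feature_a == tfs[i], , drop = FALSE]
    rt <- correlate(expr[tfs[i], ], tgt, method = config$method,
                    feature_a = tfs[i], feature_b = target_gene)
    if (all(rr$ok)) {
      tsum$r_region[i] <- mean(rr$r)
      tsum$p_min[i] <- min(rr$p)
      tsum$q_min[i] <- min(rr$q)
      pass <- rr$p < config$p_threshold
      tsum$candidate[i] <- if (config$require_all_regions) all(pass) else any(pass)
    }
    tsum$r_target[i] <- rt$r
  }
  # deterministic total order; degenerate (NA) rows sink to the bottom
  key_r <- ifelse(is.na(tsum$r_region), -Inf, tsum$r_region)
  key_t <- ifelse(is.na(tsum$r_target), -Inf, tsum$r_target)
  key_p <- ifelse(is.na(tsum$p_min), Inf, tsum$p_min)
  ord <- order(-key_r, -key_t, key_p, tsum$tf)
  tsum <- tsum[ord, , drop = FALSE]
  tsum$rank <- seq_len(nrow(tsum))
  rownames(tsum) <- NULL
  list(records = records, summary = tsum, missing = missing)
}
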