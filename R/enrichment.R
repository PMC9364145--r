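# Single-sample rank-based gene-set scoring and the dual-correlation
# association filter (the pathway / immune-signature stage).
#
# The per-sample score is a fully specified ssGSEA-style running-sum
# statistic, not a kernel-density variation score: walking down a sample's
# expression-ranked gene list, in-set genes accumulate weight
# rank^tau (normalized by the in-set total) while out-of-set genes
# accumulate 1 / (n_genes - n_set); the score averages the gap between
# the two cumulative curves and lies in [-1, 1].

#' Read gene sets from a GMT file
#'
#' @param path GMT path (name, description, then member genes, tab
#'   separated).
#' @param category Attached to every set: `"pathway"` or
#'   `"immune_signature"`.
#' @return A named list of character vectors with a `category` attribute
#'   per set.
#' @export
read_gmt <- function(path, category = "pathway") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("GMT rows need name, description and >= 1 gene")
    structure(unique(f[-(1:2)]), category = category)
  })
  names(out) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1)
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Single-sample gene-set enrichment score
#'
#' For each sample, genes are ranked by expression (average ranks for
#' ties; walk order breaks exact ties by gene name for determinism).
#' Walking down the ranked list, position k contributes
#' `(P_in(k) - P_out(k)) / n_genes` to the score, where `P_in` is the
#' cumulative `rank^tau` weight of in-set genes (normalized by the in-set
#' total) and `P_out` the cumulative count of out-of-set genes over
#' `n_genes - n_set`.  The score lies in \[-1, 1\].  A set covering all
#' genes scores 0 by convention.
#'
#' @param expr Genes x samples log2 expression matrix.
#' @param members Character vector of member gene symbols.
#' @param tau Rank-weight exponent >= 0; 0 gives the rank-only regime
#'   (invariant to monotone transformations), default 0.25.
#' @return Named per-sample score vector, or all-`NA` with a warning when
#'   no member is present in `expr`.
#' @export
ss_enrichment <- function(expr, members, tau = 0.25) {
  stopifnot(tau >= 0)
  genes <- rownames(expr)
  inset <- genes %in% members
  n <- length(genes)
  out <- setNames(rep(NA_real_, ncol(expr)), colnames(expr))
  if (!any(inset)) {
    warning("gene set has no member in the expression matrix; score undefined")
    return(out)
  }
  n_set <- sum(inset)
  if (n_set == n) {
    out[] <- 0
    return(out)
  }
  for (s in seq_len(ncol(expr))) {
    x <- expr[, s]
    ord <- order(-x, genes)                 # descending walk, name-stable
    rk <- rank(x, ties.method = "average")  # ascending: top gene ~ n
    w <- rk^tau
    w_in <- ifelse(inset, w, 0)[ord]
    p_in <- cumsum(w_in) / sum(w_in)
    p_out <- cumsum(!inset[ord]) / (n - n_set)
    out[s] <- sum(p_in - p_out) / n
  }
  out
}

#' Score a collection of gene sets per sample
#'
#' @param expr Genes x samples expression matrix.
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param tau Rank-weight exponent; see [ss_enrichment()].
#' @return Sets x samples score matrix (rows of undefined sets are `NA`).
#' @export
score_gene_sets <- function(expr, sets, tau = 0.25) {
  m <- t(vapply(sets, function(g) ss_enrichment(expr, g, tau),
                numeric(ncol(expr))))
  dimnames(m) <- list(names(sets), colnames(expr))
  m
}

#' Dual-correlation association of signature scores with a TF and target
#'
#' Each set's score vector is correlated with the TF expression and with
#' the target expression; a set passes when `r > r_threshold` and
#' `p < p_threshold` for BOTH.  The filter is symmetric in the TF and
#' target arguments.  Output is sorted by `min(r_tf, r_target)`
#' descending.
#'
#' @param scores Sets x samples score matrix.
#' @param tf_expr,target_expr Sample-aligned expression vectors.
#' @param config A [screen_config()] supplying the thresholds and method.
#' @return Data.frame: `set`, `r_tf`, `p_tf`, `r_target`, `p_target`,
#'   `r_min`, `pass`.
#' @export
associate_gene_sets <- function(scores, tf_expr, target_expr,
                                config = screen_config()) {
  if (ncol(scores) != length(tf_expr) || ncol(scores) != length(target_expr)) {
    stop("scores, tf_expr and target_expr must be sample-aligned")
  }
  rows <- lapply(rownames(scores), function(nm) {
    sc <- scores[nm, ]
    if (any(is.na(sc))) {
      return(data.frame(set = nm, r_tf = NA_real_, p_tf = NA_real_,
                        r_target = NA_real_, p_target = NA_real_,
                        r_min = NA_real_, pass = FALSE,
                        stringsAsFactors = FALSE))
    }
    a <- correlate(sc, tf_expr, method = config$method, feature_a = nm,
                   feature_b = "tf")
    b <- correlate(sc, target_expr, method = config$method, feature_a = nm,
                   feature_b = "target")
    pass <- isTRUE(a$ok) && isTRUE(b$ok) &&
      a$r > config$r_threshold && b$r > config$r_threshold &&
      a$p < config$p_threshold && b$p < config$p_threshold
    data.frame(set = nm, r_tf = a$r, p_tf = a$p, r_target = b$r,
               p_target = b$p, r_min = suppressWarnings(min(a$r, b$r)),
               pass = pass, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  key <- ifelse(is.na(out$r_min), -Inf, out$r_min)
  out <- out[order(-key, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
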