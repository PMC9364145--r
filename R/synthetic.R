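# Synthetic paired ATAC/RNA cohorts with a planted regulator.
#
# The generator encodes the causal chain the screen is designed to detect:
# a latent per-sample activity drives (i) the regulator's own expression,
# (ii) accessibility of the target's promoter, and (iii) target expression
# through that accessibility.  Decoy TFs are independent of the latent
# activity, so recovering the planted regulator from the screen is a
# well-posed parameter-recovery problem with known ground truth.

#' Ground truth for a synthetic cohort
#'
#' @param regulator_gene,target_gene Distinct gene symbols.  Defaults name
#'   the planted regulator after a STAT-family TF and the target after an
#'   immune-checkpoint ligand so the synthetic cohort plugs directly into
#'   [build_inflammatory_panel()].
#' @param alpha Effect of the latent activity on regulator log2
#'   expression.
#' @param beta Effect of the latent activity on target-promoter log2
#'   accessibility.
#' @param gamma Effect of the accessibility deviation on target log2
#'   expression.
#' @param noise_sd_expr,noise_sd_acc Gaussian noise SDs (log2 units),
#'   strictly positive.
#' @param seed Integer RNG seed used by the generators.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(regulator_gene = "STAT2", target_gene = "CD274",
                            alpha = 1.5, beta = 1.5, gamma = 1.5,
                            noise_sd_expr = 0.5, noise_sd_acc = 0.5,
                            seed = 7L) {
  if (!all(is.finite(c(alpha, beta, gamma)))) {
    stop("effect sizes alpha, beta, gamma must be finite")
  }
  if (noise_sd_expr <= 0 || noise_sd_acc <= 0) stop("noise SDs must be > 0")
  if (identical(regulator_gene, target_gene)) {
    stop("regulator and target genes must differ")
  }
  structure(list(regulator_gene = regulator_gene, target_gene = target_gene,
                 alpha = alpha, beta = beta, gamma = gamma,
                 noise_sd_expr = noise_sd_expr, noise_sd_acc = noise_sd_acc,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Cohort shape and peak-geometry configuration
#'
#' Defaults emulate a modest patient cohort: 41 samples, 20 decoy TFs, a
#' 500 bp promoter peak with ~25 bp boundary jitter and 5% per-sample peak
#' dropout, on two 1 Mb synthetic chromosomes.
#'
#' @param n_samples Number of samples, >= 3.
#' @param n_genes Total genes in the annotation (>= n_decoy_tfs + 2).
#' @param n_decoy_tfs Decoy TFs whose expression is independent of the
#'   latent activity.
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @param promoter_peak_width Width of the planted promoter peak (bp).
#' @param peak_jitter_sd SD of the Gaussian boundary jitter (bp).
#' @param peak_dropout_rate Probability in \[0, 1) that a sample's promoter
#'   peak is absent.
#' @param n_background_peaks Background peaks per sample, placed away from
#'   promoters.
#' @param depth_sd SD (log2 units) of the per-sample sequencing-depth
#'   factor multiplying every peak signal; 0 disables depth effects.
#' @param gene_spacing Minimum TSS spacing (bp) used when placing genes.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 41, n_genes = 100, n_decoy_tfs = 20,
                          chrom_sizes = c(chr1 = 1000000L, chr2 = 1000000L),
                          promoter_peak_width = 500, peak_jitter_sd = 25,
                          peak_dropout_rate = 0.05, n_background_peaks = 20,
                          depth_sd = 0.3, gene_spacing = 6000) {
  if (n_samples < 3) stop("n_samples must be >= 3")
  if (any(chrom_sizes <= 0) || is.null(names(chrom_sizes))) {
    stop("chrom_sizes must be a named vector of positive lengths")
  }
  if (peak_dropout_rate < 0 || peak_dropout_rate >= 1) {
    stop("peak_dropout_rate must lie in [0, 1)")
  }
  if (n_genes < n_decoy_tfs + 2) stop("n_genes must cover target, regulator and decoys")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_decoy_tfs = as.integer(n_decoy_tfs),
                 chrom_sizes = chrom_sizes,
                 promoter_peak_width = as.integer(promoter_peak_width),
                 peak_jitter_sd = peak_jitter_sd,
                 peak_dropout_rate = peak_dropout_rate,
                 n_background_peaks = as.integer(n_background_peaks),
                 depth_sd = depth_sd,
                 gene_spacing = as.integer(gene_spacing)),
            class = "cohort_config")
}

decoy_names <- function(truth, config) {
  panel <- build_inflammatory_panel()$symbol
  pool <- setdiff(panel, c(truth$regulator_gene, truth$target_gene))
  n <- config$n_decoy_tfs
  if (truth$regulator_gene %in% panel && n <= length(pool)) {
    pool[seq_len(n)]
  } else {
    sprintf("DECOY_TF_%02d", seq_len(n))
  }
}

#' Generate a synthetic gene annotation
#'
#' Places the target gene, the regulator, the decoy TFs and filler genes
#' on the configured chromosomes with a minimum TSS spacing; the first two
#' genes are forced onto opposite strands so both strands are always
#' represented.
#'
#' @param config A [cohort_config()].
#' @param truth A [synthetic_truth()] (supplies gene names).
#' @param seed Integer seed; defaults to `truth$seed`.
#' @return A gene model data.frame (`gene`, `chrom`, `tss`, `strand`).
#' @export
generate_annotation <- function(config, truth = synthetic_truth(),
                                seed = truth$seed) {
  set.seed(seed)
  decoys <- decoy_names(truth, config)
  n_fill <- config$n_genes - 2L - length(decoys)
  genes <- c(truth$target_gene, truth$regulator_gene, decoys,
             if (n_fill > 0) sprintf("GENE_%04d", seq_len(n_fill)))
  sp <- config$gene_spacing
  slots <- do.call(rbind, lapply(names(config$chrom_sizes), function(cn) {
    L <- config$chrom_sizes[[cn]]
    pos <- seq(sp, L - sp, by = sp)
    if (L <= 2 * sp) pos <- integer()
    if (!length(pos)) return(NULL)
    data.frame(chrom = cn, tss = as.integer(pos), stringsAsFactors = FALSE)
  }))
  if (is.null(slots) || nrow(slots) < length(genes)) {
    stop(sprintf("chromosomes too short: %d TSS slots at %d bp spacing for %d genes",
                 if (is.null(slots)) 0L else nrow(slots), sp, length(genes)))
  }
  pick <- slots[sample.int(nrow(slots), length(genes)), ]
  strand <- sample(c("+", "-"), length(genes), replace = TRUE)
  strand[1:2] <- c("+", "-")
  data.frame(gene = genes, chrom = pick$chrom, tss = pick$tss,
             strand = strand, stringsAsFactors = FALSE)
}

target_promoter_window <- function(truth, config, annotation) {
  i <- match(truth$target_gene, annotation$gene)
  tss0 <- annotation$tss[i] - 1L  # 0-based
  w <- config$promoter_peak_width
  c(start0 = tss0 - w %/% 2L, end0 = tss0 - w %/% 2L + w,
    chrom = annotation$chrom[i])
}

#' Generate a paired expression / accessibility cohort
#'
#' Per sample `s`: latent activity `a_s ~ N(0, 1)`; regulator log2
#' expression `= base + alpha * a_s + noise`; target-promoter log2
#' accessibility `= base + beta * a_s + noise`; target log2 expression
#' `= base + gamma * (accessibility deviation) + noise`.  Decoy and filler
#' genes are base + noise, independent of `a_s`.  Each sample's peak set
#' holds a promoter peak over the target promoter (boundaries jittered by
#' `Normal(0, peak_jitter_sd)`, rounded, truncated at chromosome bounds,
#' linear-scale signal `2^accessibility`) unless dropped out, plus
#' uniform background peaks placed away from all promoter windows.  All of
#' a sample's peak signals are multiplied by a per-sample depth factor
#' `2^N(0, depth_sd)`, which depth-aware normalization must remove.
#'
#' @param truth A [synthetic_truth()].
#' @param config A [cohort_config()].
#' @param annotation Gene models from [generate_annotation()]; must
#'   contain the regulator and target genes.
#' @param seed Integer seed; defaults to `truth$seed`.
#' @return A list: `expr` (genes x samples log2 matrix), `accessibility`
#'   (named per-sample log2 vector for the target promoter), `peak_sets`
#'   (named list of peak `GRanges`), `latent` (the activities), plus the
#'   `truth`, `config` and `annotation` used.
#' @export
generate_cohort <- function(truth, config = cohort_config(),
                            annotation = generate_annotation(config, truth),
                            seed = truth$seed) {
  if (!all(c(truth$regulator_gene, truth$target_gene) %in% annotation$gene)) {
    stop("annotation must contain the regulator and target genes")
  }
  if (!all(is.finite(c(truth$alpha, truth$beta, truth$gamma)))) {
    stop("effect sizes must be finite")
  }
  set.seed(seed)
  n <- config$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  genes <- annotation$gene
  a <- rnorm(n)

  base_expr <- rnorm(length(genes), mean = 8, sd = 1.5)
  names(base_expr) <- genes
  expr <- matrix(rnorm(length(genes) * n, sd = truth$noise_sd_expr),
                 nrow = length(genes), dimnames = list(genes, samples))
  expr <- expr + base_expr

  base_acc <- 5
  acc <- base_acc + truth$beta * a + rnorm(n, sd = truth$noise_sd_acc)
  names(acc) <- samples

  expr[truth$regulator_gene, ] <- base_expr[truth$regulator_gene] +
    truth$alpha * a + rnorm(n, sd = truth$noise_sd_expr)
  expr[truth$target_gene, ] <- base_expr[truth$target_gene] +
    truth$gamma * (acc - base_acc) + rnorm(n, sd = truth$noise_sd_expr)

  pw <- target_promoter_window(truth, config, annotation)
  chrom <- pw[["chrom"]]
  L <- as.integer(config$chrom_sizes[[chrom]])
  prom_all <- promoter_windows(annotation, upstream = 2000, downstream = 500)
  dropped <- runif(n) < config$peak_dropout_rate
  depth <- 2^rnorm(n, sd = config$depth_sd)  # per-sample depth factor

  # promoter peaks: boundaries jittered independently, truncated at bounds
  j1 <- as.integer(round(rnorm(n, sd = config$peak_jitter_sd)))
  j2 <- as.integer(round(rnorm(n, sd = config$peak_jitter_sd)))
  ps <- pmax(0L, as.integer(pw[["start0"]]) + j1)
  pe <- pmin(L, as.integer(pw[["end0"]]) + j2)
  pe <- pmax(pe, ps + 1L)

  # background peaks for all samples at once, redrawn while they touch a
  # promoter window
  nb <- config$n_background_peaks
  w <- config$promoter_peak_width
  nbt <- n * nb
  bc <- character(nbt); bs <- integer(nbt)
  if (nbt > 0) {
    todo <- seq_len(nbt)
    for (try in 1:50) {
      bc[todo] <- sample(names(config$chrom_sizes), length(todo),
                         replace = TRUE)
      bl <- as.numeric(config$chrom_sizes[bc[todo]])
      bs[todo] <- as.integer(floor(runif(length(todo)) * pmax(bl - w, 1)))
      cand <- GRanges(factor(bc, levels = names(config$chrom_sizes)),
                      IRanges(bs + 1L, bs + w))
      bad <- countOverlaps(cand, prom_all, ignore.strand = TRUE) > 0
      todo <- which(bad)
      if (!length(todo)) break
    }
    bsig <- 2^rnorm(nbt, mean = 5, sd = 1)
  }

  # assemble all samples' peaks in one container, then split per sample
  keep <- which(!dropped)
  sample_of <- c(keep, rep(seq_len(n), each = nb))
  all_ch <- c(rep(chrom, length(keep)), bc)
  all_s0 <- c(ps[keep], bs)
  all_e0 <- c(pe[keep], if (nbt > 0) bs + w else integer())
  all_sig <- c(2^acc[keep], if (nbt > 0) bsig else numeric()) *
    depth[sample_of]
  ord <- order(sample_of)
  all_gr <- peaks(all_ch[ord], all_s0[ord], all_e0[ord],
                  name = "peak", signal = all_sig[ord])
  idx <- factor(samples[sample_of[ord]], levels = samples)
  mcols(all_gr)$name <- sprintf("%s_peak_%03d", as.character(idx),
                                sequence(tabulate(idx, nbins = n)))
  peak_sets <- as.list(split(all_gr, idx))
  names(peak_sets) <- samples
  list(expr = expr, accessibility = acc, peak_sets = peak_sets, latent = a,
       truth = truth, config = config, annotation = annotation)
}

#' Plant a PWM consensus into a sequence
#'
#' Writes the PWM consensus (argmax base per column; reverse-complemented
#' for the minus strand) into the sequence at `at` (1-based), leaving the
#' rest untouched.
#'
#' @param sequence A character string over A/C/G/T/N.
#' @param pwm A [pwm_from_counts()] object.
#' @param at 1-based start position; `at + ncol - 1` must fit.
#' @param strand `"+"` or `"-"`.
#' @return The modified sequence (character).
#' @export
plant_motif <- function(sequence, pwm, at, strand = "+") {
  L <- ncol(pwm$matrix)
  if (at < 1 || at + L - 1 > nchar(sequence)) {
    stop("motif window out of sequence bounds")
  }
  cons <- pwm_consensus(pwm)
  if (strand == "-") {
    cons <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  }
  paste0(substr(sequence, 1, at - 1), cons,
         substr(sequence, at + L, nchar(sequence)))
}

#' Generate random chromosome sequences
#'
#' Uniform A/C/G/T sequences matching `config$chrom_sizes`, used as the
#' scanning substrate for motif fixtures.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A named character vector of sequences.
#' @export
generate_genome <- function(config, seed = 1L) {
  set.seed(seed)
  vapply(names(config$chrom_sizes), function(cn) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_sizes[[cn]],
                 replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate synthetic ChIP-seq peaks for the planted regulator
#'
#' One peak over the target promoter (centre jittered by
#' `Normal(0, jitter_sd)`) plus `n_background` uniform peaks excluding the
#' promoter window.
#'
#' @param truth A [synthetic_truth()].
#' @param annotation Gene models containing the target gene.
#' @param config A [cohort_config()] (peak width, chromosome sizes).
#' @param jitter_sd Centre jitter SD in bp.
#' @param n_background Number of background peaks.
#' @param seed Integer seed; defaults to `truth$seed`.
#' @return A peak `GRanges`.
#' @export
generate_chip_peaks <- function(truth, annotation, config = cohort_config(),
                                jitter_sd = 50, n_background = 100,
                                seed = truth$seed) {
  set.seed(seed)
  pw <- target_promoter_window(truth, config, annotation)
  chrom <- pw[["chrom"]]
  L <- as.integer(config$chrom_sizes[[chrom]])
  w <- config$promoter_peak_width
  shift <- as.integer(round(rnorm(1, sd = jitter_sd)))
  s0 <- max(0L, min(L - w, as.integer(pw[["start0"]]) + shift))
  ch <- chrom; st <- s0; en <- s0 + w; sig <- 100
  if (n_background > 0) {
    prom <- GRanges(factor(chrom, levels = names(config$chrom_sizes)),
                    IRanges(as.integer(pw[["start0"]]) + 1L,
                            as.integer(pw[["end0"]])))
    bc <- character(n_background); bs <- integer(n_background)
    todo <- seq_len(n_background)
    for (try in 1:50) {
      bc[todo] <- sample(names(config$chrom_sizes), length(todo),
                         replace = TRUE)
      bl <- as.numeric(config$chrom_sizes[bc[todo]])
      bs[todo] <- as.integer(floor(runif(length(todo)) * pmax(bl - w, 1)))
      cand <- GRanges(factor(bc, levels = names(config$chrom_sizes)),
                      IRanges(bs + 1L, bs + w))
      todo <- which(countOverlaps(cand, prom) > 0)
      if (!length(todo)) break
    }
    ch <- c(ch, bc); st <- c(st, bs); en <- c(en, bs + w)
    sig <- c(sig, round(runif(n_background, 10, 90), 1))
  }
  peaks(ch, st, en, name = sprintf("chip_%03d", seq_along(ch)), signal = sig)
}

#' Write a synthetic cohort to disk
#'
#' Emits one narrowPeak file per sample, the expression TSV, the gene
#' annotation as BED6 (1 bp TSS intervals), the per-sample promoter
#' accessibility TSV, and the ground truth as JSON.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pk <- file.path(dir, "peaks")
  dir.create(pk, showWarnings = FALSE)
  for (s in names(cohort$peak_sets)) {
    write_peaks(cohort$peak_sets[[s]],
                file.path(pk, paste0(s, ".narrowPeak")), "narrowPeak")
  }
  write_expression(cohort$expr, file.path(dir, "expression.tsv"))
  write_gene_models(cohort$annotation, file.path(dir, "annotation.bed"))
  write.table(data.frame(sample = names(cohort$accessibility),
                         log2_accessibility = cohort$accessibility),
              file.path(dir, "promoter_accessibility.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(cohort$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
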