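# End-to-end orchestration: simulate a cohort to disk, then run
# consensus -> accessibility -> screen -> motif/ChIP -> enrichment with a
# JSON manifest (parameters + input checksums) and a plain-text report.

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end screen.  `input_dir` must contain
#' the layout written by [simulate_cohort()] (or equivalent files):
#' `peaks/*.narrowPeak`, `expression.tsv`, `annotation.bed`,
#' `chrom_sizes.tsv`, and optionally `genome.fa`, `motif.pfm`,
#' `chip.narrowPeak`, `gene_sets.gmt`.
#'
#' @param input_dir Cohort directory.
#' @param out_dir Output directory for artifacts.
#' @param target_gene Target gene symbol (mandatory).
#' @param upstream,downstream Promoter window extents (bp).
#' @param min_support Consensus support fraction in (0, 1].
#' @param fixed_width Standardized consensus region width (bp); `NULL`
#'   keeps raw runs.
#' @param screen A [screen_config()].
#' @param motif_threshold_frac Motif hit threshold as a fraction of the
#'   PWM's maximal score.
#' @param n_perm Permutations for the ChIP overlap test.
#' @param tau Enrichment rank-weight exponent.
#' @param seed Integer seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir, target_gene = "CD274",
                            upstream = 2000, downstream = 500,
                            min_support = 0.9, fixed_width = 500,
                            screen = screen_config(),
                            motif_threshold_frac = 0.8, n_perm = 1000,
                            tau = 0.25, seed = 7L) {
  if (is.null(target_gene) || !nzchar(target_gene)) {
    stop("pipeline config requires a target_gene")
  }
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 target_gene = target_gene, upstream = upstream,
                 downstream = downstream, min_support = min_support,
                 fixed_width = fixed_width, screen = screen,
                 motif_threshold_frac = motif_threshold_frac,
                 n_perm = as.integer(n_perm), tau = tau,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

read_chrom_sizes <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("chrom", "size"))
  setNames(as.integer(df$size), df$chrom)
}

#' A built-in STAT-like interferon-response PFM (synthetic)
#'
#' A 9 bp GAS-like element (consensus `TTCCGGGAA`) assembled in code as a
#' reproducible offline fixture; it is NOT a database motif.
#'
#' @return A `pwm` object.
#' @export
default_pfm <- function() {
  cons <- c("T", "T", "C", "C", "G", "G", "G", "A", "A")
  counts <- matrix(1, nrow = 4, ncol = length(cons),
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(cons)) counts[cons[j], j] <- 17
  pwm_from_counts(counts, pseudocount = 0, name = "GAS_like_synthetic")
}

write_pfm <- function(pwm, path, counts_scale = 20) {
  lines <- c(paste0(">", pwm$name),
             vapply(c("A", "C", "G", "T"), function(b) {
               paste(b, "[", paste(round(pwm$matrix[b, ] * counts_scale),
                                   collapse = "  "), "]")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a cohort to disk with the pipeline layout
#'
#' Wraps the synthetic-data generators: writes per-sample narrowPeak
#' files, the expression TSV, the annotation BED6, chromosome sizes, a
#' genome FASTA with the regulator's motif consensus planted in the target
#' promoter, the motif PFM, synthetic ChIP peaks, latent-activity-derived
#' gene sets (GMT), the ground-truth JSON and a manifest.
#'
#' @param truth A [synthetic_truth()].
#' @param config A [cohort_config()].
#' @param dir Output directory.
#' @param seed Integer seed; defaults to `truth$seed`.
#' @return The generated cohort (invisibly), as from [generate_cohort()].
#' @export
simulate_cohort <- function(truth = synthetic_truth(),
                            config = cohort_config(), dir,
                            seed = truth$seed) {
  if (config$n_samples < 3) stop("n_samples must be >= 3")
  annotation <- generate_annotation(config, truth, seed = seed)
  cohort <- generate_cohort(truth, config, annotation, seed = seed)
  write_cohort(cohort, dir)
  write.table(data.frame(names(config$chrom_sizes),
                         as.integer(config$chrom_sizes)),
              file.path(dir, "chrom_sizes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  pfm <- default_pfm()
  write_pfm(pfm, file.path(dir, "motif.pfm"))
  genome <- generate_genome(config, seed = seed)
  pw <- target_promoter_window(truth, config, annotation)
  at <- as.integer(pw[["start0"]]) + config$promoter_peak_width %/% 2L + 1L
  genome[[pw[["chrom"]]]] <- plant_motif(genome[[pw[["chrom"]]]], pfm, at, "+")
  writeLines(unlist(lapply(names(genome), function(cn) {
    c(paste0(">", cn), substring(genome[[cn]],
                                 seq(1, nchar(genome[[cn]]), 70),
                                 pmin(seq(1, nchar(genome[[cn]]), 70) + 69,
                                      nchar(genome[[cn]]))))
  })), file.path(dir, "genome.fa"))
  chip <- generate_chip_peaks(truth, annotation, config, seed = seed + 1L)
  write_peaks(chip, file.path(dir, "chip.narrowPeak"), "narrowPeak")
  # pathway fixtures: one set of activity-driven genes (regulator + target),
  # one independent control set
  sets <- list(ACTIVITY_DRIVEN_SYNTHETIC = c(truth$regulator_gene,
                                             truth$target_gene),
               RANDOM_CONTROL_SYNTHETIC = grep("^GENE_",
                                               cohort$annotation$gene,
                                               value = TRUE)[1:10])
  write_gmt(sets, file.path(dir, "gene_sets.gmt"))
  jsonlite::write_json(list(stage = "simulate", seed = seed,
                            n_samples = config$n_samples,
                            files = list.files(dir, recursive = TRUE)),
                       file.path(dir, "simulate_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cohort)
}

read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' Run the full screen end to end
#'
#' Stages, in order: consensus-region calling over the per-sample peak
#' sets, promoter assignment to the target gene, accessibility
#' quantification and normalization, the TF correlation screen, motif
#' scanning of the consensus regions (when a genome and PFM are present),
#' the ChIP overlap permutation test (when ChIP peaks are present), and
#' gene-set association (when a GMT is present).  All artifacts plus a
#' JSON manifest (parameters, input checksums) and a report are written
#' under `config$out_dir`.  Reruns with identical config and inputs are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return A list of stage results (invisibly): `regions`, `acc`,
#'   `screen`, `motif_hits`, `chip_test`, `associations`, `report_path`.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ind <- config$input_dir
  outd <- config$out_dir
  dir.create(outd, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  manifest <- list(config = unclass_recursive(config), stages = list(),
                   complete = FALSE)
  on.exit({
    manifest$failed_stage <- if (manifest$complete) NULL else stage
    jsonlite::write_json(manifest, file.path(outd, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
  })
  tryCatch({
    stage <- "inputs"
    peak_files <- sort(list.files(file.path(ind, "peaks"),
                                  pattern = "\\.narrowPeak$",
                                  full.names = TRUE))
    if (!length(peak_files)) stop("no narrowPeak files under peaks/")
    peak_sets <- lapply(peak_files, read_peaks, dialect = "narrowPeak")
    names(peak_sets) <- sub("\\.narrowPeak$", "", basename(peak_files))
    expr <- read_expression(file.path(ind, "expression.tsv"))
    genes <- read_gene_models(file.path(ind, "annotation.bed"))
    chrom_sizes <- read_chrom_sizes(file.path(ind, "chrom_sizes.tsv"))
    checked <- c(peak_files, file.path(ind, c("expression.tsv",
                                              "annotation.bed",
                                              "chrom_sizes.tsv")))
    manifest$inputs <- as.list(tools::md5sum(checked))

    stage <- "consensus"
    t0 <- proc.time()[["elapsed"]]
    regions <- consensus_regions(peak_sets, min_support = config$min_support,
                                 fixed_width = config$fixed_width,
                                 chrom_sizes = chrom_sizes)
    assign <- assign_promoters(regions, genes, config$upstream,
                               config$downstream)
    write_consensus(regions, file.path(outd, "consensus.bed"))
    write.table(assign, file.path(outd, "promoter_assignment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    target_idx <- which(!is.na(assign$gene) & assign$gene == config$target_gene)
    if (!length(target_idx)) {
      stop("no consensus region maps to the target promoter: ",
           config$target_gene)
    }
    target_regions <- regions[target_idx]
    log_stage("consensus", t0)

    stage <- "accessibility"
    t0 <- proc.time()[["elapsed"]]
    raw <- quantify_accessibility(target_regions, peak_sets)
    # QC: a sample with no called peak in any target region carries no
    # accessibility measurement (peak dropout is censoring, not zero
    # openness); such samples are excluded from the screen, not scored 0
    censored <- colnames(raw$values)[colSums(raw$values > 0) == 0]
    if (length(censored)) {
      message("[atacscreen] censoring ", length(censored),
              " sample(s) with no peak in the target regions: ",
              paste(censored, collapse = ", "))
      keep <- setdiff(colnames(raw$values), censored)
      raw <- accessibility_matrix(raw$regions,
                                  raw$values[, keep, drop = FALSE], "raw")
    }
    manifest$censored_samples <- as.list(censored)
    # depth from each sample's full peak library, not the few target regions
    lib <- vapply(peak_sets, function(p) sum(mcols(p)$signal), numeric(1))
    acc <- normalize_accessibility(raw, "cpm_log2", size_factors = lib)
    write_accessibility(acc, file.path(outd, "accessibility.tsv"))
    log_stage("accessibility", t0)

    stage <- "screen"
    t0 <- proc.time()[["elapsed"]]
    panel <- build_inflammatory_panel()
    scr <- screen_tfs(expr, acc, panel, config$target_gene, config$screen)
    write.table(scr$records, file.path(outd, "screen_records.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(scr$summary, file.path(outd, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("screen", t0)

    stage <- "motif"
    motif_hits <- NULL
    fa <- file.path(ind, "genome.fa")
    pf <- file.path(ind, "motif.pfm")
    if (file.exists(fa) && file.exists(pf)) {
      t0 <- proc.time()[["elapsed"]]
      genome <- read_fasta_seqs(fa)
      pwm <- read_jaspar_pfm(pf)[[1]]
      thr <- config$motif_threshold_frac * pwm_max_score(pwm)
      hits_by_region <- lapply(seq_along(target_regions), function(i) {
        r <- target_regions[i]
        seqc <- substr(genome[[as.character(seqnames(r))]], start(r), end(r))
        h <- scan_pwm(seqc, pwm, threshold_bits = thr)
        if (nrow(h)) cbind(region = format_region(r), h) else NULL
      })
      motif_hits <- do.call(rbind, hits_by_region)
      if (is.null(motif_hits)) {
        motif_hits <- data.frame(region = character(), start = integer(),
                                 end = integer(), strand = character(),
                                 score = numeric(), match = character())
      }
      write.table(motif_hits, file.path(outd, "motif_hits.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      log_stage("motif", t0)
    }

    stage <- "chip"
    chip_test <- NULL
    cp <- file.path(ind, "chip.narrowPeak")
    if (file.exists(cp)) {
      t0 <- proc.time()[["elapsed"]]
      chip <- read_peaks(cp, "narrowPeak")
      chip_test <- chip_overlap_test(chip, target_regions, chrom_sizes,
                                     n_perm = config$n_perm,
                                     seed = config$seed)
      jsonlite::write_json(chip_test[c("observed", "p_value", "n_perm")],
                           file.path(outd, "chip_overlap.json"),
                           auto_unbox = TRUE, digits = NA)
      log_stage("chip", t0)
    }

    stage <- "enrichment"
    assoc <- NULL
    gmt <- file.path(ind, "gene_sets.gmt")
    if (file.exists(gmt)) {
      t0 <- proc.time()[["elapsed"]]
      sets <- read_gmt(gmt)
      scores <- score_gene_sets(expr, sets, tau = config$tau)
      top_tf <- scr$summary$tf[1]
      assoc <- associate_gene_sets(scores, expr[top_tf, ],
                                   expr[config$target_gene, ],
                                   config$screen)
      write.table(assoc, file.path(outd, "associations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      log_stage("enrichment", t0)
    }

    stage <- "report"
    top <- scr$summary[1, ]
    rep_lines <- c(
      sprintf("Top candidate regulator: %s (mean region r = %.3f, r vs %s expression = %.3f, min p = %.3g)",
              top$tf, top$r_region, config$target_gene, top$r_target,
              top$p_min),
      sprintf("Consensus regions mapped to %s promoter: %s",
              config$target_gene,
              paste(format_region(target_regions), collapse = ", ")),
      if (!is.null(motif_hits)) {
        sprintf("Motif hits (>= %.0f%% of max score) in target regions: %d",
                100 * config$motif_threshold_frac, nrow(motif_hits))
      },
      if (!is.null(chip_test)) {
        sprintf("ChIP overlap: observed %d / %d regions, permutation p = %.4g",
                chip_test$observed, length(target_regions),
                chip_test$p_value)
      },
      if (!is.null(assoc)) {
        sprintf("Gene sets passing the dual filter (r > %.2f, p < %.2f): %s",
                config$screen$r_threshold, config$screen$p_threshold,
                if (any(assoc$pass)) paste(assoc$set[assoc$pass],
                                           collapse = ", ") else "none")
      })
    report_path <- file.path(outd, "report.txt")
    writeLines(rep_lines, report_path)
    manifest$complete <- TRUE
    invisible(list(regions = target_regions, acc = acc, screen = scr,
                   motif_hits = motif_hits, chip_test = chip_test,
                   associations = assoc, report_path = report_path))
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

log_stage <- function(name, t0) {
  message(sprintf("[atacscreen] %-14s %6.2fs", name,
                  proc.time()[["elapsed"]] - t0))
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}

#' Command-line entry point
#'
#' Subcommands (flags mirror [pipeline_config()]; logs on stderr, results
#' only in files):
#' \describe{
#'   \item{simulate}{`--out DIR [--seed N] [--n-samples N]` - write a
#'     synthetic cohort.}
#'   \item{run}{`--in DIR --out DIR [--target GENE] [--seed N]` - the full
#'     pipeline.}
#'   \item{consensus}{`--in DIR --out FILE.bed [--min-support F]
#'     [--fixed-width W]` - consensus regions from `DIR/peaks`.}
#'   \item{quantify}{`--in DIR --regions FILE.bed --out FILE.tsv` -
#'     normalized accessibility over regions.}
#'   \item{screen}{`--expr FILE.tsv --acc FILE.tsv --target GENE
#'     --out FILE.tsv` - the TF panel screen.}
#'   \item{motif}{`--fasta FILE --pfm FILE --chrom NAME --from POS
#'     --to POS --out FILE.tsv` - PWM scan of one region.}
#'   \item{chip}{`--chip FILE --regions FILE.bed --sizes FILE.tsv
#'     --out FILE.json [--n-perm N] [--seed N]` - overlap permutation
#'     test.}
#'   \item{enrich}{`--expr FILE.tsv --gmt FILE --tf GENE --target GENE
#'     --out FILE.tsv` - gene-set scores and the dual filter.}
#' }
#'
#' @param args Character vector of CLI arguments; defaults to
#'   `commandArgs(trailingOnly = TRUE)`.
#' @return Exit status 0 invisibly (errors raise conditions).
#' @export
atacscreen_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: atacscreen <simulate|run|consensus|quantify|screen|motif|chip|enrich> [options]"
  if (!length(args)) stop(usage)
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  req <- function(flag) {
    v <- opt(flag)
    if (is.null(v)) stop(cmd, " requires ", flag)
    v
  }
  seed <- as.integer(opt("--seed", "7"))
  load_peaks_dir <- function(ind) {
    pf <- sort(list.files(file.path(ind, "peaks"),
                          pattern = "\\.narrowPeak$", full.names = TRUE))
    if (!length(pf)) stop("no narrowPeak files under ", ind, "/peaks")
    ps <- lapply(pf, read_peaks, dialect = "narrowPeak")
    names(ps) <- sub("\\.narrowPeak$", "", basename(pf))
    ps
  }
  switch(cmd,
    simulate = {
      n <- as.integer(opt("--n-samples", "41"))
      simulate_cohort(synthetic_truth(seed = seed),
                      cohort_config(n_samples = n), req("--out"), seed = seed)
    },
    run = {
      run_screen(pipeline_config(req("--in"), req("--out"),
                                 target_gene = opt("--target", "CD274"),
                                 seed = seed))
    },
    consensus = {
      ind <- req("--in")
      sizes <- read_chrom_sizes(file.path(ind, "chrom_sizes.tsv"))
      regs <- consensus_regions(load_peaks_dir(ind),
                                min_support = as.numeric(opt("--min-support", "0.9")),
                                fixed_width = as.integer(opt("--fixed-width", "500")),
                                chrom_sizes = sizes)
      write_consensus(regs, req("--out"))
    },
    quantify = {
      ind <- req("--in")
      regs <- read_peaks(req("--regions"), "bed6")
      ps <- load_peaks_dir(ind)
      lib <- vapply(ps, function(p) sum(mcols(p)$signal), numeric(1))
      acc <- normalize_accessibility(quantify_accessibility(granges(regs), ps),
                                     "cpm_log2", size_factors = lib)
      write_accessibility(acc, req("--out"))
    },
    screen = {
      expr <- read_expression(req("--expr"))
      acc <- read_accessibility(req("--acc"))
      scr <- screen_tfs(expr, acc, build_inflammatory_panel(),
                        req("--target"))
      write.table(scr$summary, req("--out"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    },
    motif = {
      genome <- read_fasta_seqs(req("--fasta"))
      pwm <- read_jaspar_pfm(req("--pfm"))[[1]]
      from <- as.integer(req("--from")); to <- as.integer(req("--to"))
      h <- scan_pwm(substr(genome[[req("--chrom")]], from, to), pwm)
      write.table(h, req("--out"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    },
    chip = {
      res <- chip_overlap_test(read_peaks(req("--chip"), "narrowPeak"),
                               granges(read_peaks(req("--regions"), "bed6")),
                               read_chrom_sizes(req("--sizes")),
                               n_perm = as.integer(opt("--n-perm", "1000")),
                               seed = seed)
      jsonlite::write_json(res[c("observed", "p_value", "n_perm")],
                           req("--out"), auto_unbox = TRUE, digits = NA)
    },
    enrich = {
      expr <- read_expression(req("--expr"))
      scores <- score_gene_sets(expr, read_gmt(req("--gmt")))
      assoc <- associate_gene_sets(scores, expr[req("--tf"), ],
                                   expr[req("--target"), ])
      write.table(assoc, req("--out"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    },
    stop(usage))
  invisible(0L)
}
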