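# atacscreen

Integrative ATAC-seq + RNA-seq screening for upstream transcription
factors of a target gene.

## The problem

Which transcription factor (TF) drives the expression of a gene of
interest — say, an immune-checkpoint ligand such as PD-L1/CD274 — in a
patient cohort?  When paired chromatin-accessibility (ATAC-seq) and
expression (RNA-seq) profiles are available, a direct upstream regulator
should leave a triple signature:

1. reproducible open-chromatin regions in the target's promoter across
   the cohort;
2. correlation between the TF's expression and the accessibility of
   those promoter regions (and with target expression);
3. physical evidence of binding: the TF's sequence motif inside the
   regions and ChIP-seq peaks overlapping them.

`atacscreen` implements this screen as a reusable pipeline for
bioinformaticians working on regulatory genomics, with a curated
inflammatory TF panel (the NF-κB, IRF and STAT families — 21 TFs), and a
synthetic-cohort generator with a *planted* regulator so every stage can
be validated offline with known ground truth.

## The method

For samples *s = 1…n*, consensus regions are maximal runs of bases
covered by peaks from ≥ ⌈`min_support`·n⌉ distinct samples (default 90%),
optionally standardized to fixed 500 bp windows and assigned to
strand-aware promoter windows (−2000/+500 bp around the TSS by default).
Accessibility of region *R* in sample *s* is the overlap-weighted signal
sum Σ_peaks signal·(overlap/width), depth-normalized (CPM, log2).  Each
panel TF is then scored by the product-moment correlation

r = cov(x_TF, a_R) / (sd(x_TF)·sd(a_R)),  t = r·√((n−2)/(1−r²))

with two-sided p from the t distribution (Spearman available), BH
step-up q-values across all (TF, region) tests, and a deterministic
ranking (mean per-region r, then r vs target expression, then p, then
symbol).  Candidates are validated by log2-odds PWM scanning of the
region sequence (both strands, N-windows skipped) and by a
width-preserving uniform-permutation test of ChIP-peak overlap,
p = (1 + #{null ≥ obs})/(n_perm + 1).  Finally, gene sets are scored per
sample with a rank-based running-sum statistic (ssGSEA-style, exponent
τ = 0.25) and kept when they correlate with **both** the TF and the
target (r > 0.4 and p < 0.05).

The synthetic generator encodes the causal chain the screen assumes: a
latent activity a_s ~ N(0,1) drives regulator expression (effect α),
target-promoter accessibility (β) and, through accessibility, target
expression (γ), with Gaussian log2 noise, decoy TFs, per-sample depth
factors, peak-boundary jitter and peak dropout.

## Worked example

```r
library(atacscreen)

d <- file.path(tempdir(), "cohort"); o <- file.path(tempdir(), "out")
simulate_cohort(synthetic_truth(seed = 7), cohort_config(), d)   # 41 samples
res <- run_screen(pipeline_config(d, o, seed = 7))
head(res$screen$summary[, c("tf","family","r_region","r_target","p_min","candidate","rank")], 5)
```

```
     tf family r_region r_target    p_min candidate rank
1 STAT2   STAT    0.856    0.822 7.31e-12      TRUE    1
2   REL  NF-kB    0.371    0.398 2.17e-02      TRUE    2
3  IRF1    IRF    0.252    0.247 1.28e-01     FALSE    3
4  IRF7    IRF    0.196    0.147 2.39e-01     FALSE    4
5 STAT1   STAT    0.192    0.139 2.47e-01     FALSE    5
```

The report (`out/report.txt`):

```
Top candidate regulator: STAT2 (mean region r = 0.856, r vs CD274 expression = 0.822, min p = 7.31e-12)
Consensus regions mapped to CD274 promoter: chr2:797762-798261
Motif hits (>= 80% of max score) in target regions: 1
ChIP overlap: observed 1 / 1 regions, permutation p = 0.06793
Gene sets passing the dual filter (r > 0.40, p < 0.05): ACTIVITY_DRIVEN_SYNTHETIC
```

Reading it: the planted regulator (`STAT2` by default) tops the ranking
with mean correlation 0.86 between its expression and the accessibility
of the consensus promoter region (p ≈ 7e-12 across n = 41 samples, minus
any censored dropout samples); the region carries a maximal-score motif
hit; the synthetic ChIP peak overlaps it; and the activity-driven gene
set passes the dual-correlation filter while the random control does
not.  Decoy TFs scatter around r ≈ 0, below the candidate gate.

A command-line interface mirrors the stages
(`simulate`, `run`, `consensus`, `quantify`, `screen`, `motif`, `chip`,
`enrich`):

```sh
Rscript inst/cli/atacscreen simulate --out cohort --seed 7
Rscript inst/cli/atacscreen run --in cohort --out results --seed 7
```

## Vignette

`vignettes/methods.Rmd` documents the model, the defaults and why, the
synthetic world and its limits, and the numerical choices.
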