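---
title: "Methods: screening for upstream transcription factors with paired ATAC-seq and RNA-seq"
author: "atacscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for upstream transcription factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The model

`atacscreen` asks a causal question — which transcription factor (TF)
regulates a target gene? — and answers it with correlational and
physical evidence, combined.  The underlying generative picture is a
chain: a latent per-sample regulatory activity $a_s$ (interferon tone,
inflammatory state, …) drives the regulator's own expression, opens the
target's promoter chromatin, and thereby raises target transcription:

$$x^{reg}_s = \mu_r + \alpha\, a_s + \varepsilon_s,\qquad
  c_s = \mu_c + \beta\, a_s + \eta_s,\qquad
  x^{tgt}_s = \mu_t + \gamma\,(c_s - \mu_c) + \delta_s,$$

with $a_s \sim N(0,1)$ and independent Gaussian noise on the log2 scale.
Under this model the regulator's expression and the target-promoter
accessibility are correlated with
$\rho = \alpha\beta / \sqrt{(\alpha^2+\sigma^2_{expr})(\beta^2+\sigma^2_{acc})}$,
which is what the screen estimates; decoy TFs, independent of $a_s$,
have $\rho = 0$.  The screen therefore assumes (i) the samples are
exchangeable (no batch or copy-number structure), (ii) expression and
accessibility are on a roughly log-linear scale, and (iii) a promoter
window captures the regulatory contact.  None of these identify
causality by themselves — the package's validation stages (motif
presence, ChIP overlap) supply the physical-binding half of the
argument, exactly as the screen's design intends.

# Pipeline stages and their parameters

## Consensus open-chromatin regions

A base is *supported* when covered by peaks from at least
$\lceil m \cdot n \rceil$ distinct samples; maximal supported runs are
the consensus regions, optionally standardized to a fixed width centred
on the run midpoint.

* `min_support` (fraction, default **0.9**): "reproducible across the
  cohort" has no canonical quantitative meaning; 90% tolerates the
  dropout a peak caller produces while still demanding near-cohort-wide
  evidence.  Duplicate peaks within a sample never add support.
* `fixed_width` (bp, default **500**): promoter-scale open regions are a
  few hundred bp; a fixed width makes accessibility values comparable
  across regions and matches the scale at which promoter regions are
  conventionally reported.
* Promoter window: **−2000/+500 bp** around the TSS, strand-aware (the
  mirror image on the minus strand).  A common default in promoter
  annotation tools; exposed because no universal value exists.

## Accessibility quantification and normalization

The accessibility of region $R$ in sample $s$ is
$\sum_{p \in peaks_s} signal(p)\cdot \frac{|p \cap R|}{|p|}$ — an
overlap-weighted signal sum.  It is additive under peak splitting,
robust to boundary jitter, and exactly checkable against a per-bp
rasterization oracle; counts or maxima would be neither.  Normalization
is CPM + log2(x+1) per sample.  Because a screen matrix may hold only
one or two target regions, the pipeline passes each sample's *whole
library* signal total as the scaling denominator (`size_factors`);
scaling by the column totals of a two-row matrix would erase exactly the
between-sample variation the screen measures.

**Censoring rather than zero.** A sample with no called peak in any
target region contributes no measurement: at 5% peak dropout,
log2(0+1) = 0 values sit ~15 log2 units below the column mean and can
single-handedly flip a Pearson ranking.  The pipeline excludes such
samples from the screen (they are listed in the manifest); the
lower-level `quantify` API keeps the documented "no overlap → 0"
behaviour.

## The correlation screen

The panel is the union of the three inflammatory TF families: NF-κB
(NFKB1, NFKB2, RELA, RELB, REL), IRF1–9, and STAT1–4/5A/5B/6 — 21
symbols.  Pearson on log-scale values is the default (Spearman
available); the two-sided p uses the exact t transform on $n-2$ degrees
of freedom.  Benjamini–Hochberg q-values are computed over all
(TF, region) tests and reported alongside raw p, but the candidate gate
is raw **p < 0.05** per region (in *every* region by default,
`require_all_regions`), keeping the screen's operating characteristics
transparent.  Ranking uses a four-level deterministic key — mean
per-region r (descending), r versus target expression (descending),
minimum region p (ascending), symbol — so reruns and platform changes
cannot reorder ties.  The mean-over-regions aggregation is a ranking
convenience; per-region records are always emitted.  Zero-variance
expression columns yield flagged records (`ok = FALSE`), are excluded
from candidacy, and sink to the bottom of the ranking instead of
erroring the run.

## Motif and ChIP validation

PWMs come from JASPAR-style count matrices with
$p(b,j) = (n_{bj} + \kappa)/(N_j + 4\kappa)$ (pseudocount $\kappa$,
default 0.25); windows score
$\sum_j \log_2 p(b_j, j)/q(b_j)$ against the background $q$ (uniform by
default), N-containing windows are skipped, and the minus strand is
scanned through the reverse-complemented matrix with coordinates mapped
back.  The default hit threshold is **80% of the PWM's maximal
achievable score** — motif "presence" needs a cutoff even when none is
published, and a maximal-score fraction adapts to motif information
content.  The ChIP test re-places each region uniformly
(width-preserving) on its own chromosome and uses the add-one estimator
$p = (1 + \#\{null \ge obs\})/(n_{perm}+1)$, which cannot return 0 and
is super-uniform under the null.

## Gene-set association

The per-sample score walks the expression-ranked gene list and averages
the gap between the cumulative in-set weight ($rank^\tau$, normalized)
and the cumulative out-of-set count; it lies in $[-1, 1]$, and
$\tau = 0.25$ (the common ssGSEA choice, exposed) mildly emphasizes
extreme ranks while $\tau = 0$ is fully rank-only and hence invariant to
monotone transformations.  This simple, exactly specified statistic
replaces kernel-density variation scoring on purpose: the downstream
claims rest on the *correlation pattern* of the scores, not on a
particular smoother, and the running sum has a hand-checkable oracle.  A
set covering all genes scores 0 by convention; a set with no member in
the matrix is flagged undefined.  A signature passes the dual filter
when it correlates with **both** the candidate TF and the target
(r > 0.4 and p < 0.05) — the filter is symmetric in the two.

# The synthetic world

`synthetic_truth()` / `cohort_config()` defaults *are* the stated test
world: 41 samples, 20 decoy TFs, effect sizes $\alpha=\beta=\gamma=1.5$,
noise SD 0.5 (log2), a 500 bp promoter peak with 25 bp boundary jitter,
5% peak dropout, 20 background peaks per sample, a $2^{N(0,0.3)}$
per-sample depth factor, and two 1 Mb chromosomes.  The defaults not
fixed by the design (base expression $N(8, 1.5)$, background signal
$2^{N(5,1)}$, 6 kb TSS spacing) were chosen once as plausible for
log-FPKM-scale cohort data and are documented here rather than tuned.

What the generator emulates: the causal chain above, cohort-scale
sampling noise, library-depth variation, peak-boundary jitter and
dropout, decoys, a plantable motif consensus and a promoter-binding ChIP
profile.  What it does not: count-level (negative-binomial) noise,
fragment-size structure, GC/width bias, batch effects, copy-number
variation, correlated TF modules, or realistic genome composition.  A
green recovery test therefore establishes that the pipeline's inference
machinery is correct and calibrated *under its own model* — not that the
screen is robust to everything real cohorts do.

# Numerical and degenerate-input choices

* Coordinates: 0-based half-open on disk (BED), 1-based closed in
  memory (GRanges) and in all displayed coordinates — the two
  conventions coincide on display.
* Fixed-width midpoint: floor of the 0-based run midpoint; windows are
  trimmed at chromosome edges (never shifted), so a window near an edge
  may be shorter than requested.
* Promoter ties: nearest |region midpoint − TSS| wins; exact ties go to
  the lexicographically smallest symbol.
* Correlation: r is clamped to [−1, 1] before the t transform; |r| = 1
  maps to p = 0; zero-variance input is flagged, not an error.
* BH: step-up with min-over-tail, capped at 1; NA p-values (flagged
  records) propagate as NA.
* Permutation p: add-one correction on both counts.
* RNG: every `generate_*` call and every stochastic stage takes an
  explicit integer seed and uses a single global stream; identical
  (truth, config, seed) gives byte-identical artifacts.

# Known limitations

* Correlation screens cannot distinguish a direct regulator from a
  tightly co-regulated passenger; the motif and ChIP stages mitigate but
  do not remove this.
* The accessibility statistic inherits the peak caller's behaviour;
  there is no read-level (BAM) counting path.
* The dual filter uses raw p at fixed n; with many signatures the
  expected number of false passes grows, and the emitted q-values should
  be consulted for large collections.
* The CLI reads flags, not a config file; the JSON manifest written with
  every run records the full configuration and input checksums and
  suffices to reproduce a run.
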