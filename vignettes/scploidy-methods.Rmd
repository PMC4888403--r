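---
title: "Calling whole-chromosome copy number in shallow single-cell WGS: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling whole-chromosome copy number in shallow single-cell WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Shallow single-cell whole-genome sequencing of sorted nuclei — on the order
of a few hundred thousand uniquely mapped reads per cell, from libraries
prepared without whole-genome pre-amplification — carries enough information
to count whole chromosomes. Because every genomic locus is represented at
most twice in a diploid nucleus and losses during library preparation are
close to random, the read count in a sufficiently large genomic bin is
nearly proportional to the underlying DNA copy number. `scploidy`
implements the full analysis chain from aligned reads (or a count matrix)
to cohort-level aneuploidy statistics, plus a synthetic-data generator that
emulates such libraries so the entire chain is testable without sequencing
data.

## Binning and count preprocessing

Reads are counted in non-overlapping bins of variable width (~1 Mb mean)
constructed so every bin holds the same amount of uniquely mappable
sequence: bin width is inversely proportional to local mappability
(`build_variable_bins()` cuts a mappability track into equal-mass bins;
`simulate_bin_grid()` generates such grids de novo). Reads enter a bin by
their leftmost mapped position (0-based, half-open intervals everywhere;
BED on disk); reads flagged duplicate and reads with MAPQ below 11 (i.e.
anything not strictly above 10) are discarded first. With 50 nt reads and
megabase bins, fractional-overlap assignment would change nothing, so it is
not attempted.

Two multiplicative corrections follow.

**GC correction.** Counts depend smoothly on bin GC fraction. The trend is
estimated and divided out, with two safeguards that matter more than the
choice of smoother:

* *The trend must not absorb copy-number signal.* If a haploid chromosome
  happens to occupy one end of the GC range (male chrY is small enough for
  this to occur on a scaled genome), a plain count-vs-GC regression bends
  toward its half-depth bins and the "correction" doubles them back toward
  disomy. `gc_correct()` therefore backfits two components: robust
  per-chromosome median levels (the copy signal, never divided out) and the
  GC trend proper, fitted to level-normalized counts. Three backfit
  iterations are ample at these sizes.
* *Zeros stay zero.* The correction is multiplicative, so nullisomy
  evidence survives for the caller's delta state.

The smoother is a robust local quadratic regression (`loess`, span 0.3,
`family = "symmetric"`) when at least 200 bins are available — locally
linear smoothers cannot invert a quadratic bias shape within a few percent
at the edges of the GC range, which is why degree 2 is used — and a
GC-decile median ratio on smaller grids. Corrected totals are rescaled to
the raw total, so the correction redistributes mass but never creates or
destroys it.

**Mappable-mass normalization.** The realized grid records each bin's
actual `mappability x width` mass. On full-scale genomes these masses are
equal to a fraction of a percent, but on scaled-down genomes the integer
number of bins per chromosome quantizes the per-chromosome mass by up to
~10 %, which a copy-number caller would read as signal (a trisomic
chromosome at -7 % mass sits exactly at the 2.5-copy decode boundary).
`normalize_mappable_mass()` divides counts by relative bin mass,
total-preserving. It is a no-op when bins truly are equal-mass.

## The copy-number model

Corrected counts, rounded to integers, are the observations of a hidden
Markov model along the ordered bins with states $s \in \{0, 1, \dots, 10\}$
(nullisomy up to decasomy). Emissions are tied to a single pair of
monosomy parameters $(\mu_1, \sigma_1^2)$:

* state 0 emits a point mass at zero (no smoothing; a single nonzero count
  vetoes nullisomy),
* state $s \ge 1$ emits a negative binomial with mean $s\mu_1$ and variance
  $s\sigma_1^2$.

This tying has a convenient closed form: the NB success probability
$p = \mu_1/\sigma_1^2$ is shared by all states and the size parameter
$r_s = s\,\mu_1^2/(\sigma_1^2 - \mu_1)$ is linear in $s$, which the test
suite asserts on every fitted model. It also makes the model identifiable
from a single cell: one depth parameter, one dispersion parameter, and the
chain.

Parameters are estimated by Baum-Welch. Transition and initial
distributions get the standard exact updates. For the tied emissions the
M-step uses posterior-weighted moment matching of the scaled observations
$c_i/s$ — closed-form and almost always optimal — but moment matching is
not an exact maximizer of the expected complete-data log-likelihood, and
can produce likelihood decreases of order $10^{-5}$ relative. The update is
therefore accepted only when it improves that objective; otherwise a short
numerical refinement runs and the best candidate (including the unchanged
current parameters) wins. This keeps the generalized-EM ascent guarantee,
and the suite asserts monotonicity of the likelihood trace to a relative
$10^{-6}$.

Numerics: forward-backward runs with per-bin scaling (300+ bins underflow
otherwise); the delta state's log-mass is exactly $-\infty$ for nonzero
counts. Initialization assumes a near-diploid cell ($\mu_1 =$ mean of
nonzero counts / 2; variance floored at $1.2\mu_1$ so the NB is defined;
0.99 self-transition; initial mass concentrated on states 1-4). The
variance floor during fitting is $1.05\mu_1$. Convergence is a relative
log-likelihood change below $10^{-4}$ (cap 200 iterations; typical cells
converge in 3-10).

Decoding assigns each bin the state with the highest posterior probability;
ties break toward the state nearer 2, then the smaller state — conservative
toward euploidy and deterministic. Viterbi decoding is available
(`decoding = "viterbi"`) but is not the default. An all-zero cell
short-circuits to all-nullisomy with likelihood 1, flagged.

## Quality control

Five per-library metrics: genomic coverage (fraction of bins with a
nonzero count — a binned-data notion, not base-level coverage), spikiness
($\sum_i |c_{i+1}-c_i| / \sum_i c_i$ over consecutive bins in grid order),
Shannon entropy of the read distribution over bins (nats), the number of
maximal constant-state segments (never crossing a chromosome boundary), and
the Bhattacharyya distance
$-\ln \sum_k \sqrt{P_1(k) P_2(k)}$ between the fitted monosomy and disomy
emissions, summed until the residual tail mass is below $10^{-12}$ —
a direct measure of how separable adjacent copy-number states are in that
library.

Libraries are then clustered per sample on the five standardized metrics
(agglomerative, complete linkage). The number of clusters (at most 4) is
chosen by average silhouette width with two guards: singleton clusters get
silhouette 0 (Rousseeuw's convention — otherwise one outlier cell becomes
the "best cluster" and the rest of a good sample fails), and a cut is
accepted only if it beats the best silhouette obtainable after
independently permuting the metric columns (20 permutations, fixed internal
seed), so a homogeneous sample stays one cluster instead of being split on
noise. Clustering is per sample because each sample is one individual of
one sex, and pooling samples would let sex-linked coverage differences
(chrY bins are empty in female cells) masquerade as quality structure.
Within the selected (best mean quality) cluster, a cell passes only if it
also satisfies the absolute thresholds spikiness < 0.21 and Bhattacharyya
distance > 1.0; everything outside the selected cluster fails.

Library complexity is estimated from the downsampling saturation curve
$u(s) = C_{\max} s / (K + s)$ — the Michaelis-Menten form, fitted by
`nls`/`SSmicmen` with a Levenberg-Marquardt fallback — at 10 evenly spaced
subsample depths. On the fitted curve $u(K) = C_{\max}/2$ identically.
Non-saturating data (unique = sequenced throughout) are flagged rather than
extrapolated. Note the estimator's regime-dependence: when sequencing
probes the molecule pool several times over, $C_{\max}$ recovers the pool
size within a few percent; when the pool is sampled less than once on
average, the hyperbola extrapolates far beyond the observed depths and its
asymptote should be read as a rough upper-scale figure.

## Karyotyping and cohort statistics

A chromosome's copy number is the modal decoded state over its bins (by bin
count; bins hold equal mappable content by construction, so base-pair
weighting would be nearly identical), ties again toward disomy then the
smaller state, with the supporting fraction reported. A cell is aneuploid
iff at least one chromosome deviates from its sex-aware expectation —
autosomes 2; X/Y of (2, 0) for XX and (1, 1) for XY, so male X monosomy is
normal. Sex is taken from metadata when recorded, otherwise inferred from
the X/Y calls; an irreconcilable pattern demotes the cell to autosome-only
classification, flagged. Sub-chromosomal segments change nothing unless
they flip the modal state. `focal_scan()` reports decoded states of bins
overlapping a region (the GRCh37 APP locus, chr21:27,252,861-27,543,446, is
shipped as a preset) to expose focal gains the whole-chromosome call would
hide.

Prevalences are reported as percentages with exact Clopper-Pearson binomial
intervals (`binom.test`); per-sample percentages round to 2 decimals and
pooled cohort figures to 1, with unrounded values alongside. Per-chromosome
gain/loss rates count each cell once per affected chromosome. Group
comparisons use the two-sided Wilcoxon rank-sum test: exact enumeration
when both groups have at most 10 values and no ties, otherwise the normal
approximation with continuity and tie corrections; degenerate all-equal
inputs return p = 1. Only QC-passing cells enter any numerator or
denominator.

## The synthetic-data generator

`simulate_cell()` draws bin counts from exactly the generative model the
caller assumes: bin $i$ on a chromosome with programmed copy number $s$ is
NB with mean $s\,u\,g(\mathrm{gc}_i)\,m_i w_i/\bar w$ and size
$s \cdot \mathrm{dispersion}$, where $u$ is set so the expected total
equals the configured depth. Sharing the tied-moment structure between
simulator and caller is deliberate: it makes parameter recovery well-posed,
so decoding failures in tests indicate real defects rather than model
mismatch. Defaults are the study conditions: 333,000 expected uniquely
mapped reads per cell, and a recorded sequenced-read total inflated by the
study's empirical duplication factor (858,800/333,000).

Choices where realism needed a decision:

* **Dispersion 100** (NB size of the monosomy unit): gives a disomic-bin
  coefficient of variation of ~8 % at study depth, so good-tier cells land
  at spikiness ~0.15-0.19 and Bhattacharyya ~4-7 — comfortably passing the
  thresholds, as the study's accepted libraries did, without being
  noise-free. The noisy tier divides dispersion by 10 and inflates 5 % of
  bins fivefold, which reliably fails both thresholds.
* **GC bias** is a multiplicative quadratic in GC, unit mean,
  $1 + 1.5(\mathrm{gc}-0.41) - 6(\mathrm{gc}-0.41)^2$, floored at 0.1:
  roughly ±25 % over the realistic GC range. A clearly detectable
  confounder (raw count-GC correlation well away from zero) that GC
  correction must remove, but of the moderate amplitude expected from a
  protocol without pre-amplification; steeper curves collapse low-GC bins
  toward zero rate, which no smooth trend can invert.
* **GC is spatially autocorrelated** (stationary AR(1) along each
  chromosome, mean 0.41, sd 0.05, lag-1 correlation 0.8, clipped to
  [0.25, 0.60]): megabase-scale GC in real genomes varies smoothly, and an
  independent draw per bin would overstate bin-to-bin variation, inflating
  spikiness for reasons that have nothing to do with library quality.
* **Mappability** per bin is Beta(9, 1.5) (mean ~0.86) unless overridden;
  bin widths are set from a global mass quantum so mappable content per bin
  is equal genome-wide, then each chromosome is divided into exactly
  equal-mass bins (see the normalization note above for why).
* **Duplicate structure** is uniform sampling with replacement from a
  molecule pool (`simulate_duplicate_library()`), i.e. the classical
  occupancy process.

All randomness flows from explicit seeds; per-cell seeds derive
deterministically from the cohort seed, and the generator restores the
caller's RNG state.

**What the generator does not emulate** — and therefore what passing tests
do not establish about real data: alignment and mapping artifacts
(mappability enters only through bin widths), within-bin GC effects at
fragment scale, sub-chromosomal CNVs (whole chromosomes only, plus planted
focal states in fixtures), replication-timing or strand effects, skewed
(non-uniform) molecular duplication — real complexity estimates behave
differently from the uniform occupancy model, see the regime note above —
and any cross-cell correlation (cells are independent). Results on real
libraries additionally depend on the quality of the mappability track and
duplicate marking, which this package consumes but does not produce.

## Scale of the shipped analyses

The analysis drivers and the test suite run on a genome with GRCh37
chromosome proportions scaled by 1/10 (~305 bins at 1 Mb mean) — large
enough that every chromosome keeps several bins and per-cell fits are
well-conditioned, small enough that a full cohort runs in seconds. The
headline validation cohorts keep their original sizes (36 trisomy-21 cells,
81 euploid male cells); some property checks (depth monotonicity of the QC
metrics, planted-plate pass fractions) use 6-16 cells per condition, which
is ample for the asserted effect sizes. The published cohort arithmetic
(pooled prevalences, exact intervals, per-sample percentages) is recomputed
from the printed per-sample counts and is exact at any scale.

## Known limitations

* Whole-chromosome calls only; the segment machinery exists (and feeds the
  QC segment count) but no sub-chromosomal event calling is attempted.
* The Clopper-Pearson interval is one convention among several; published
  intervals computed with other methods can differ in the last digit.
* The HMM treats the genome as a single chain (state persistence crosses
  chromosome boundaries during fitting; segments never do). With 0.99
  self-transition the effect on decoding is negligible, but it is a
  modeling shortcut.
* Estimated `dispersion` is a per-cell constant; real libraries can show
  bin-specific overdispersion that the tied model averages over.
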