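---
title: "Methods: windowed differential methylation with coherence filtering"
author: "rankmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed differential methylation with coherence filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The count model

Capture-based methylation sequencing (MBD-Seq) converts regional
methylation into read depth: the more methylated CpGs a fragment
carries, the more likely it is to be captured and sequenced. `rankmeth`
therefore works entirely on counts. The genome is tiled into
consecutive, non-overlapping windows of 300 bp — the expected fragment
size, so one fragment informs roughly one window — and the count of
window $w$ in sample $i$ is modelled as negative binomial:

$$Y_{wi} \sim \mathrm{NB}(\mu_{wi}, \phi_w), \qquad
  \mathrm{Var}(Y_{wi}) = \mu_{wi} + \phi_w \mu_{wi}^2,$$

$$\log \mu_{wi} = \log(L_i f_i) + \beta_{0w}
  + \beta_{Aw}\,[\mathrm{age}_i = \mathrm{cub}]
  + \beta_{Rw}\,[\mathrm{rank}_i = \mathrm{low}].$$

$\phi_w$ is the dispersion (the reciprocal of the shape parameter of the
underlying gamma–Poisson mixture; $\phi = 0$ recovers Poisson counts),
$L_i$ is the library size recorded as the column sum of the *unfiltered*
matrix, and $f_i$ is the TMM normalization factor. Reference levels are
*adult* and *high-ranking*, so $\beta_{Rw}$ is the low-ranking effect and
a positive value means hypermethylated in low-ranking animals. It is
reported in base 2 (logFC). The rank effect is tested per window by a
likelihood-ratio test of the full (age + rank) against the reduced
(age-only) model on 1 df, with Benjamini–Hochberg adjustment applied
once across all filtered windows genome-wide.

Model fitting, TMM and dispersion moderation are delegated to edgeR —
the standard implementation of exactly these steps — behind the
package's function surface; the merging, filtering, resampling and
comparison procedures around them are implemented here.

Key assumptions: capture efficiency per window is a fixed
window-specific constant (absorbed by $\beta_{0w}$); samples are
independent (no relatedness or clan structure is modelled); and
between-sample differences in total signal are composition bias plus
depth, which TMM plus the offset can absorb.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `window_width` | 300 bp | matches the sequenced fragment size; one fragment ≈ one window |
| `min_total` / `min_positive` | 10 / 10 | a window must carry ≥10 reads summed over samples and be non-zero in ≥10 individuals before it can support a 42-sample GLM |
| `q_threshold` | 0.05 | FDR level for declaring windows significant |
| `prior_df` | estimated | shrinkage weight of the empirical-Bayes dispersion moderation; see below |
| `K` (subsets) | 6 | leave-one-group-out with groups of 7 from 42 samples gives 35-sample subsets, large enough to refit the model |
| `alpha` (coherence) | 0.05 | per-subset significance requirement |
| `n_trees`, `n_reps` | 2000, 1000 | forest size and repetition count for the oob-error range |
| `promoter_bp` | 2000 | promoters defined as the 2 kb upstream of the TSS |

The coverage filter wording "10 reads per position" is ambiguous between
per-position and per-window readings; the implementation uses ≥10 reads
per *window* summed over samples (inclusive), which is the natural unit
once counts are windowed, and exposes both thresholds as arguments.

### The dispersion prior

The moderation shares dispersion information across windows: each
window's estimate is shrunk toward the common value with weight
`prior_df`. The default *estimates* that weight from the spread of the
per-window likelihoods (edgeR's `estimateDisp` default). This matters
for error control: pinning a moderate prior (say 10 residual df) on data
whose true dispersion is homogeneous leaves enough noise in the tagwise
estimates that windows with *underestimated* dispersion preferentially
reach small p-values — a selection effect that measurably inflates the
realized false-discovery proportion in the calibration simulations.
With the estimated prior, homogeneous data shrink essentially to the
common dispersion and the realized FDR stays at its nominal level, while
genuinely heterogeneous data retain per-window estimates. A fixed
`prior_df` remains available.

## DMR calling and the coherence filter

Significant windows (q ≤ threshold) are merged into DMRs when they are
*grid-adjacent* (the end of one window is the start of the next on the
same contig — a window removed by the coverage filter therefore breaks a
run) and share the sign of logFC. Significance is decided first and the
direction partition applied second; a window with logFC exactly 0 joins
neither direction. The DMR-level effect is the unweighted mean of member
logFCs and the significance summary is the minimum q; member windows of
one DMR always agree in direction, so the mean cannot cancel.

The coherence filter re-runs the *same* analysis — TMM factors,
dispersion estimation, full/reduced fits, LRT — within each
leave-one-group-out subset, over the frozen full-data window set (no
re-filtering), and keeps a candidate DMR only if every member window has
p ≤ 0.05 with a consistent direction in every subset. Direction
consistency additionally requires agreement with the full-data sign (the
candidate's defining direction); a flag relaxes this to among-subset
agreement only. The group partition is drawn by rejection sampling under
the constraint that every group contains at least one sample of each
rank and each age class, with group sizes as equal as possible; the seed
is recorded in the scheme. Note the subsets share $K-1$ of $K$ groups
pairwise, so the filter detects dependence on a few samples rather than
providing independent replication — a strong false positive supported by
many samples will survive it.

## Discriminative power

Four covariate sets are compared by random-forest out-of-bag error: all
candidate DMRs, the selected set, the excluded set, and the single
mean-methylation covariate (the normalization-scaled library total),
each alongside the age class. The per-DMR feature is the CPM of the
counts summed over the DMR's member windows (per-window features are
available behind a flag). Forest parameters are pinned to the common
defaults — bootstrap bags of size $n$ with replacement,
`mtry = floor(sqrt(p))`, Gini splitting, majority vote — and
deliberately untuned; each repetition derives its own RNG stream from
the seed plus the repetition index, so reports are reproducible and
order-independent. The matched-size random-location control draws the
same number of windows uniformly without replacement (optionally
excluding a set, e.g. the true DMR windows) and should hover at the
chance band, defined as the majority-class error rate ±3 binomial
standard errors.

## Age-class concordance and the mitochondrial comparison

The rank effect is re-estimated separately within cubs and adults using
rank-only models (each class with its own TMM factors and dispersions),
and the Pearson correlation of the two logFC vectors at the DMR windows
is compared with a null distribution of correlations on random window
subsets of the same size, drawn uniformly *without replacement* from all
filtered windows (window-level, not DMR-level — the draw unit the
procedure defines). The empirical p is one-sided (null ≥ observed) with
the +1 correction, so its floor is $1/(B+1)$ and it can never be zero.

The mitochondrial/nuclear comparison computes, per individual, the mean
CPM across all windows (DNA) or genes (RNA) of each compartment. The
paired mito-vs-nuclear contrasts use the Wilcoxon signed-rank test with
the standard conventions: zero differences dropped, exact null for up to
25 non-zero tie-free pairs, otherwise a normal approximation with tie
and continuity corrections; a continuity-corrected Z is always reported
alongside. If every difference is zero the result is reported as no
evidence (p = 1). The independent high-vs-low contrasts use the rank-sum
test with the same exact/approximate policy.

## The synthetic-data generator

The generator emulates the study conditions: a cohort of 42 samples in
four rank × age cells (9/9/15/9), per-window baseline rates
$\lambda_w$ (reads per million) drawn once from a base-2 log-normal
(defaults: mean 3, sd 1, i.e. a typical captured window yields ~8 reads
per million), library sizes drawn log-uniformly in 5–15 million and then
fixed as offsets, NB noise at a common dispersion $\phi = 0.2$
(moderate biological replication noise for ~40 wild samples), planted
DMRs entering multiplicatively in base 2 so the true effect sits on the
pipeline's logFC scale, and a mitochondrial contig whose windows (and
genes, in the expression matrix) get a ×10 abundance multiplier,
emulating the high mitochondrial copy number of gut epithelium. Each
matrix draws from its own RNG stream derived from the config seed plus a
fixed role offset, so adding the expression simulation never perturbs
the methylation draws and identical configs are bit-identical.

What it does *not* emulate: read-level structure (FASTQ, mapping,
duplicates), capture-efficiency or GC bias, contaminating non-host DNA,
relatedness between samples, and dispersion heterogeneity across
windows. Passing calibration tests therefore show the statistical
machinery is correct under the stated model, not that real gut-epithelium
MBD data satisfy that model.

In the calibration scenario used by the tests and the acceptance script
(5,000 windows × 42 samples, 10% of windows planted as 5-window DMRs at
|logFC| = 2), the planted directions are balanced — half hypermethylated,
half hypomethylated in low-ranking animals — as in real cohorts, where
regions shift in both directions. This is not incidental: planting 10%
of windows all in one direction concentrates ~30% of the affected
class's library mass in the planted windows, and TMM's trimmed mean then
retains an asymmetric-truncation bias of roughly $0.15\,\sigma_M$ that
shifts *every* null window's estimated effect and inflates the realized
FDR several-fold even at the true dispersion. That sensitivity is an
intrinsic property of trimmed-mean normalization under strongly
one-sided differential signal, worth knowing when interpreting real
datasets with massive unidirectional shifts.

## Numerical choices and degenerate inputs

- IRLS fits (via edgeR's Levenberg-damped scoring) with no prior count
  on the coefficients, so small-sample fits match direct likelihood
  maximization; the tests verify agreement with a brute-force optimizer
  to 4 decimals.
- Likelihood-ratio statistics that are negative by numerical noise (up
  to $10^{-6}$) are clamped to zero; anything worse raises an error.
- The last window of a contig is truncated to the contig end and kept,
  so window lengths per contig always sum to the contig length.
- Promoters truncate at contig bounds (possibly to zero length, in which
  case they are dropped). Minus-strand promoters extend to higher
  coordinates by default; a strand-naive mode always extends to lower
  coordinates, since annotation pipelines differ on this point.
- Coordinates are 0-based half-open internally; GFF3 I/O converts
  to/from 1-based inclusive; BED stays 0-based. The TSS is stored as a
  1-bp interval, and "overlapping the TSS" means covering that base.
- A sample with all-zero counts fails TMM with an error naming the
  sample; an empty matrix filters to an empty matrix without error; an
  empty candidate list yields an empty DMR table.

## Problem sizes in the test suite

The calibration tests run 3 null datasets and 20 planted replicates at
5,000 windows × 42 samples, 20 recovery replicates at 500 windows, one
coherence experiment at 600 windows with 30 planted DMRs and 30 null
pseudo-candidates, and the discriminative-power contrast with 50
repetitions of 500-tree forests — sizes chosen so the full suite
completes in about a minute while keeping Monte-Carlo error well inside
the asserted margins. The oob-error defaults for real analyses remain
2000 trees × 1000 repetitions.

## Known limitations

- The LRT is mildly liberal at moderate counts compared with
  quasi-likelihood F-tests (deliberately out of scope); the calibration
  simulation quantifies the realized FDR instead of assuming it.
- The coherence filter is a sample-dependence screen, not replication.
- Gene models are treated as single-isoform (union of exons; first exon
  = 5'-most); multi-isoform structure collapses.
- Mean-methylation comparisons between compartments inherit CPM's
  compositionality: a true abundance increase in one compartment
  necessarily depresses the other's CPM share.
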