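---
title: "Methods: a cellularity-aware methylation analysis and classification pipeline"
author: "methylforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cellularity-aware methylation analysis and classification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylforge)
```

# Scope and rationale

`methylforge` re-implements, as a tested and reusable pipeline, a
genome-wide DNA methylation analysis of tumor versus adjacent benign
tissue on Illumina 450k-style arrays: probe and sample quality control,
beta/M-value transforms, per-probe association of methylation with tumor
cellularity using empirical-Bayes moderated statistics, bump-hunted
differentially methylated regions (DMRs) with resampling family-wise
error control, copy-number inference from total signal intensities, and
construction of a minimal CpG logistic classifier. Because the original
tumor cohorts live in controlled repositories, every stage is exercised
against a synthetic cohort generator with known ground truth; the
generator is first-class, tested code, and its defaults define the study
conditions used by the test suite and by `scripts/acceptance.R`.

# The measurement model

A 450k-style array reports, per CpG probe and sample, a methylated
intensity $M$ and unmethylated intensity $U$. Methylation level is the
**beta value**

$$\beta = \frac{M}{M + U + \alpha},$$

with stabilizing offset $\alpha = 100$ by default (the literature
convention; configurable, and the assays themselves do not dictate a
value). Beta is bounded and interpretable; for inference we use the
**M-value** $\mathrm{Mv} = \log_2(\beta / (1-\beta))$, whose variance is
approximately constant across the methylation range. The logit is clipped
at $\varepsilon = 10^{-6}$ so M-values are always finite, and the inverse
transform recovers the clipped beta to $10^{-10}$.

## Probe and sample quality control

A probe is removed when its detection p-value exceeds 0.01 in at least
one sample (the strictest reading of the usual rule; a
fraction-of-samples policy is available via `det_policy = "fraction"`),
or when it is flagged as containing a SNP at the interrogated site. Both
reasons are recorded in the QC report, detection taking precedence when
both apply.

Sample-level screening follows the two customary checks. First, a
genome-wide methylation density check: a good sample's beta distribution
is bimodal (unmethylated mass near 0.1, methylated mass near 0.85), so
samples whose fraction of betas inside the mid-band $[0.3, 0.7]$ exceeds
0.35 are flagged. The exact criterion used in practice is visual; our
mid-band rule is an explicit, reproducible stand-in and is labeled as
such. Second, classical multidimensional scaling of
$1 - \text{Pearson correlation}$ distances into two dimensions, flagging
samples more than 5 median absolute deviations above the median distance
from the centroid. A constant matrix yields zero coordinates, a warning,
and no outliers.

# Differential methylation against tumor cellularity

Dissected tumor specimens are mixtures of tumor and non-tumor cells. If a
CpG has baseline methylation $\beta_0$ and full-tumor shift $\Delta$,
a specimen with tumor cellularity $c$ observes approximately

$$\beta_{\mathrm{obs}} = c \cdot \mathrm{clip}(\beta_0 + \Delta)
  + (1 - c)\,\beta_0,$$

so the group difference is diluted linearly by cellularity. The pipeline
therefore regresses each probe's M-value on a single continuous
covariate — the level of tumor involvement, with normals entering at 0 —
rather than on a group indicator. Ordinary least squares gives a slope,
residual variance $s_g^2$ with $d = n - 2$ degrees of freedom, and the
unscaled standard error $1/\sqrt{S_{xx}}$.

## Empirical-Bayes moderation

With tens of thousands of probes and few samples, per-probe variances are
noisy. We place the standard scaled inverse-chi-square prior
$\sigma_g^2 \sim s_0^2 d_0 / \chi^2_{d_0}$ on the true variances and
estimate $(d_0, s_0^2)$ by moment matching on $\log s_g^2$: the excess of
$\mathrm{var}(\log s_g^2)$ over the sampling component
$\psi'(d/2)$ identifies $d_0$ through a Newton inversion of the trigamma
function, and the matched mean identifies $s_0^2$. When the empirical
spread does not exceed the sampling component the prior is a point mass
($d_0 = \infty$); exactly identical variances return that common value.
Zeros are floored at the 1st percentile of the positive variances before
taking logs. The moderated statistic uses the posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d\, s_g^2)/(d_0 + d)$ and is referred to a
$t$ distribution on $d_0 + d$ degrees of freedom ($d_0 = 0$ reproduces
the ordinary $t$-test; $d_0 = \infty$ the normal-theory limit). The
estimator is cross-checked in the test suite against the corresponding
limma machinery, which is never used as the implementation.

## The call rule

Significance requires both a Bonferroni-adjusted p-value below 0.01 —
with $n$ equal to the number of probes that survived QC, not the array
total — and an absolute group methylation difference above 0.2. The
effect size is deliberately the difference of group mean betas
(tumor minus normal), not the regression slope, because that is how the
profile's effect axis is defined and how it transfers to external
cohorts. The table is sorted by adjusted p, then decreasing $|\Delta\beta|$,
with probe-id tie-breaks, so output order is deterministic.

Two profile-level sanity checks accompany the table: the Pearson
correlation between per-sample mean beta over the significant probes and
cellularity, and complete-linkage hierarchical clustering (Euclidean
distance on beta) cut at two clusters, scored against the true labels by
the adjusted Rand index.

# Differentially methylated regions

Bump hunting proceeds in four steps. (1) Probes are chained into clusters
wherever the gap to the previous probe is at most 500 bp on the same
chromosome. (2) The per-probe group difference $\Delta\beta$ is smoothed
within clusters by a truncated running mean of window 3 — the smallest
symmetric window; the underlying method family does not pin down a
smoother, and locally weighted regression is deliberately out of scope.
(3) Candidate regions are maximal runs of $\ge 3$ consecutive probes of
common sign with $|\text{smoothed } \Delta\beta| > 0.2$; a region's value
is its mean smoothed difference, and its area ($\sum$ of absolute
smoothed values) is reported but not used for ranking, because the
selection rule quotes a value cutoff, not an area cutoff. (4) Family-wise
error rates come from resampling: under the null the group labels are
exchangeable, so we permute labels (the default; a residual-bootstrap
alternative is available), rerun the identical machinery, and record the
maximum candidate $|$value$|$ per iteration. With $B$ iterations,
$\mathrm{FWER} = (1 + \#\{\text{null max} \ge |\text{value}|\})/(B+1)$ —
the add-one form avoids zero p-values, and a warning is raised when $B$
is too small for the floor $1/(B+1)$ to resolve the reporting threshold
(0.01). Permutations are drawn in a canonical sample order (sorted
names), so shuffling input columns leaves every output bit-identical.

# Copy number from total intensity

Total intensity $T = M + U$ tracks local DNA copy number. The matrix is
quantile normalized across samples (forcing each column to the row-wise
mean of the column-sorted values, ties receiving the mean of their rank
range), divided per probe by the median over normal samples, and log10
transformed: 0 is diploid and a CN-copy segment at purity 1 sits near
$\log_{10}(\mathrm{CN}/2)$. Single-probe outliers deviating more than 4
sample standard deviations from the median of their $\pm 2$-probe
neighborhood are shrunk to that median $\pm 4$ SD, sign preserved;
chromosomes with fewer than 5 probes pass through untouched.

Each sample and chromosome is then segmented by **recursive binary
segmentation**: the candidate split maximizes the pooled two-sample $t$
statistic between left and right means (computed in $O(n)$ by cumulative
sums, minimum 2 probes per side), is accepted when its permutation
p-value — re-maximizing over shuffles of the interval's values — falls
below 0.01, and the procedure recurses on both halves. This is a
deliberate simplification of full circular binary segmentation with the
identical acceptance contract; it is verified against an exhaustive
max-$t$ oracle on short vectors, and the permutation loop stops early
once acceptance has become impossible. The full protocol uses 10,000
permutations per split; desk-scale runs use 500, which still resolves
p < 0.01.

Called segments need $\ge 5$ probes and a mean log ratio $> 0.2$ (gain)
or $< -0.3$ (loss) — the asymmetric published thresholds, corresponding
to at least one copy gained or lost. Two consequences of keeping these
thresholds verbatim are worth recording. A CN = 3 gain at purity 1 has an
expected ratio of $\log_{10}(3/2) = 0.176 < 0.2$ and can never be called;
and quantile normalization attenuates ratios by a few percent, which
leaves one-copy losses (expected $-0.301$) straddling the $-0.3$ cut.
Both match the amplification-dominated character of CNV lists produced
under these rules. Calling performance is therefore exercised with
clearly callable events (CN = 4 gains and CN = 0 homozygous deletions),
while single-copy events (CN = 3, CN = 1) are tracked at the
segmentation level, where boundary and level accuracy are measured
against truth.

Tumor segments sharing a direction with an overlapping normal-sample
segment covering $\ge 50\%$ of the tumor segment's length are removed, as
are segments touching a blacklist interval (the analog of the customary
HLA-region exclusion; in synthetic coordinates the blacklist is empty by
default but the mechanism is exercised in tests). Remaining segments are
reduced per sample, and a breakpoint sweep reports maximal sub-intervals
covered by $\ge 2$ distinct tumors. Finally, recurrent intervals are
joined to the reported DMRs at $\ge 1$ bp overlap (1-based inclusive
coordinates internally; BED export converts to 0-based half-open), with a
flag for concordant hypermethylation (gain with positive regional
$\Delta\beta$).

# The minimal CpG classifier

Feature selection runs in three deterministic stages over the significant
probes. (1) Probes located inside any recurrent CNV interval are
excluded, so copy-number artifacts cannot masquerade as methylation
markers. (2) Only fully differentiating probes are kept: rank AUC
(Mann-Whitney, ties counted 1/2) exactly 1.00 in either orientation —
`max(U, 1-U)` — so a perfectly separating hypomethylated probe also
qualifies. (3) Greedy redundancy pruning in decreasing $|\Delta\beta|$
order (probe-id tie-break): a probe is kept only if its squared Pearson
correlation with every already-kept probe is at most 0.90. Each stage
raises a named error if it empties the candidate set.

The panel is fitted by **L1-regularized logistic regression**, authored
here as iteratively reweighted least squares with cyclic coordinate
descent and soft-thresholding (the numerical core is compiled C++, as is
usual for this class of solver). Features enter on the beta scale —
scores must be computable from the beta values of external cohorts —
and are standardized internally (mean 0, variance 1 with an $1/n$
denominator), with coefficients back-transformed on output; the intercept
is unpenalized. Convergence requires the maximum standardized coefficient
change across one reweighting round to fall below $10^{-7}$; the solution
satisfies the Karush-Kuhn-Tucker conditions to $10^{-4}$ and is
cross-checked against glmnet and an independent proximal-gradient
optimizer in the tests. The weight floor ($10^{-5}$) and a $\pm 30$ cap
on the linear predictor guard the separable-data regime.

The penalty is chosen by repeated stratified 5-fold cross-validation:
fold assignment is re-randomized (25 repetitions at desk scale, 1000 in
the full protocol — the "repeated randomization" reading of the published
procedure; a label-permutation reading cannot be excluded and is recorded
as an open interpretation), held-out misclassification at the 0.5
threshold is averaged, and the **largest** lambda attaining the minimum
mean error wins (parsimony tie-break). A repetition whose training folds
lose a class is re-drawn and logged. The warm-started path uses a looser
inner tolerance ($10^{-5}$), which affects held-out classifications by
far less than a grid step.

Scores are $\mathrm{logistic}(b_0 + \sum_j b_j \beta_j)$ in $(0, 1)$; a
sample is classed tumor only when its score strictly exceeds 0.5 (a score
of exactly 0.5 is classed normal, a deterministic boundary). Evaluation
reports the confusion counts, sensitivity, specificity, accuracy, and the
rank AUC of the scores.

# The synthetic cohort generator

The generator emulates the statistical structure the pipeline must
handle, with ground truth recorded for every spiked feature.

* **Manifest.** Probes over `n_chrom` chromosomes with a mixture of
  short (30-300 bp) and long (1-20 kb) gaps, so 500 bp clustering yields
  realistic cluster-size spectra; island annotation at 80%, enhancer 30%,
  SNP flags 1%.
* **Baselines.** Per-probe baseline beta from a bimodal mixture (Beta
  distributions with means 0.1 and 0.85, concentration 50); CpG islands
  are mostly unmethylated (low-mode probability 0.9, falling to 0.2 in
  open sea). Baselines and per-probe intensities are probe *biology*:
  an independent validation cohort must reuse them (the `baseline`
  argument) while re-drawing samples and noise.
* **Cellularity.** Normals at 0; tumors uniform on 0.6-0.9, the
  plausible post-macrodissection range for specimens dissected from
  areas marked at $\ge 50\%$ tumor content. With spike $\Delta = 0.3$,
  the expected diluted difference is $0.75 \times 0.3 = 0.225$, placing
  the study conditions deliberately close to the 0.2 call threshold.
* **Spikes.** 500 DMPs at $\Delta = 0.3$ (99% hypermethylated, mirroring
  the overwhelmingly hypermethylated profile), placed on low-baseline,
  SNP-free probes so the effect is expressible; eight regional bumps
  occupying whole 10-15-probe clusters of uniformly low baseline
  (island-wide hypermethylation — a sub-cluster bump would be diluted by
  the truncated smoother at its edges, a property of the smoother, not
  of the data); recurrent CNV truth of three CN = 4 gains and two CN = 0
  deletions spanning 120 consecutive probes each (megabase-scale events,
  the regime in which intensity-based calling from methylation arrays is
  reliable, and the size class a top-down segmenter can detect inside a
  multi-thousand-probe chromosome), carried by 8 of 31 tumors, with 50
  DMPs placed inside the gains (none inside homozygous deletions — a
  deleted locus has no DNA to methylate); plus CN = 3 and CN = 1
  segments (3 carriers, no DMPs) used solely to measure segmentation
  boundary/level accuracy.
* **Noise.** Measurement noise is additive Gaussian on the M-value
  (log2 logit) scale, sd 0.3 M-units — the typical technical-replicate
  magnitude for these arrays — then back-transformed, which keeps beta
  inside $(0,1)$ without clipping. Total intensity is log-normal with
  median 3000 (per-probe sd 0.5, per-observation sd 0.1 on the log
  scale), multiplied by CN/2 inside a carrier's truth segments.
  Detection p-values are below 0.005 except for probe-by-sample failures
  at rate $5 \times 10^{-4}$ (drawn above 0.02), so the any-sample
  filter rule is genuinely exercised. Optional technical replicates
  re-draw only the noise terms.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: batch and chip-position
effects, dye bias, control-probe behavior, cross-reactive probes,
genuine genomic probe coordinates or island tracks, correlated biological
(as opposed to technical) variation between neighboring CpGs beyond the
spiked regions, purity-dependent copy-number dilution (CN scaling is
applied at purity 1), and intensity distributions of real scanners
(log-normal is an assumption, documented, not claimed as faithful).

# Numerical and reproducibility choices

Quantile normalization uses average ranks with linear interpolation into
the reference distribution, matching the "ties share the mean of their
rank range" contract exactly (and verified against limma's
implementation). Zero denominators in the beta computation return 0 with
a warning; zero normal medians in the log-ratio step are floored to the
smallest positive median; all-zero probes are flagged and excluded.
Segmentation handles zero-variance intervals by assigning $t = \infty$
to a genuine mean difference and $t = 0$ otherwise. One master seed
expands into fixed per-stage sub-seeds (`stage_seed()`), so stages are
independently reproducible and a rerun with the same configuration is
bit-identical; all artifacts are stamped with the seed and a canonical
configuration hash.

Desk-scale problem sizes, used by the test suite, the analysis drivers
and the acceptance script, are the package's default study conditions:
a 20,000-probe, 8-chromosome manifest; 16 normals and 31 tumors; an
independent 100-sample validation cohort; $B = 200$ resampling
iterations for DMR FWERs; 500 permutations per segmentation split; and
25 cross-validation repetitions. The full-protocol settings (1000
bootstrap iterations, 10,000 permutations, 1000 repetitions) are one
flag away (`scale = "full"`).

# Known limitations

* The detection-filter scope, beta offset, bimodality criterion and
  smoothing parameters are conventions where the published protocol is
  silent; all are configurable and the defaults are recorded above.
* Top-down binary segmentation cannot detect very short embedded
  segments (tens of probes inside thousands); the circular two-change
  scan that addresses this is out of scope, and the truth design uses
  large events instead.
* Real-cohort headline numbers (thousands of DMPs, hundreds of DMRs,
  a specific four-CpG panel) are properties of real tumor data and are
  emulated qualitatively, not reproduced.
* Single-copy losses sit at the $-0.3$ calling threshold by
  construction; their recovery is measured at the segmentation level.
* No gene-set enrichment, protein-interaction hotspot or TF-motif
  analysis: these require external annotation databases and are outside
  the pipeline's scope.
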