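# methylforge

Genome-wide DNA methylation analysis of tumor versus adjacent benign
tissue on Illumina 450k-style arrays, built as a reusable R package plus
a numbered analysis workflow. It is aimed at computational biologists who
want a tested, fully reproducible implementation of the classic
FFPE-tumor methylation protocol: QC and normalization, cellularity-aware
differential methylation, bump-hunted differentially methylated regions
(DMRs) with resampling family-wise error control, copy-number inference
from array signal intensities, and a minimal CpG diagnostic classifier —
all exercised on a synthetic cohort generator with known ground truth, so
no controlled-access data are needed.

## The model in brief

Per probe, methylation is the beta value β = M/(M + U + α) and inference
runs on M-values log2(β/(1−β)). Because dissected tumor specimens are
cell mixtures, a CpG with full-tumor shift Δ is observed diluted by tumor
cellularity c:

    β_obs = c·clip(β₀ + Δ) + (1 − c)·β₀

so each probe's M-value is regressed on c (normals at 0), variances are
shrunk with the empirical-Bayes scaled inverse-χ² prior (moment matching
on log s², trigamma inversion), and probes are called at Bonferroni
p < 0.01 **and** |Δβ| > 0.2. DMRs are maximal runs (≥ 3 probes, gaps
≤ 500 bp, smoothed |Δβ| > 0.2) with label-permutation FWER
(1 + #{null max ≥ value})/(B + 1). Copy number uses quantile-normalized
total intensity referenced to the median of normals, log10 transformed,
segmented by recursive binary segmentation with permutation-tested change
points (≥ 5 probes, mean log ratio > 0.2 or < −0.3). The classifier
keeps significant probes outside recurrent CNVs with rank AUC exactly
1.00, prunes r² > 0.90 redundancy, and fits L1-regularized logistic
regression (coordinate descent, compiled core) with the penalty chosen by
repeated stratified cross-validation; scores are probabilities with a
strict 0.5 cut-off.

## Worked example

The analysis drivers under `analysis/` run the whole study on the default
synthetic cohort (20,000 probes, 16 normals / 31 tumors with cellularity
0.6–0.9, 500 spiked DMPs at Δ = 0.3, eight island-wide bumps, recurrent
CN=4/CN=0 events plus CN=3/CN=1 accuracy probes):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_diffmeth.R
Rscript analysis/04_dmr.R
Rscript analysis/05_cnv.R
Rscript analysis/06_classifier.R
```

which prints (seed 1):

```
cohort: 20000 probes x 47 samples; truth: 500 DMPs, 8 DMRs, 46 CNV carrier segments
kept 19334 of 20000 probes (484 detection, 182 snp); 47/47 samples pass bimodality, 0 MDS outliers
prior: d0 = 5.05, s0^2 = 0.0722
553 significant probes (99.1% hypermethylated); recall 0.944, 0 false positives
profile-cellularity Pearson r = 1.000; clustering ARI = 1.00
9 candidate regions, 9 reported at FWER < 0.01 (all hypermethylated: TRUE)
truth-region probe-level Jaccard: min 0.91, mean 0.99
44 called segments -> 44 after normal/blacklist filtering -> 6 recurrent intervals
single-copy recovery: max boundary error 1 probes, max level error 0.022
341 candidates after selection -> 5 active probes at lambda = 0.261
training: accuracy 1.00, AUC 1.00
validation (n = 100): sensitivity 1.00, specificity 1.00, accuracy 1.00, AUC 1.00
```

Reading it: QC removes 3.3% of probes (detection failures in any sample,
or SNP overlap); the moderation prior shrinks 19k noisy per-probe
variances toward s₀² with about five prior degrees of freedom; 553 calls
recover 94% of the spiked truth with no false positives, and the profile
mean tracks tumor cellularity essentially perfectly — the diluted-mixture
signature. All eight spiked regions are found with near-perfect probe
overlap; segmentation localizes single-copy events to within one probe
and ~0.02 log10 units; and the panel needs only 5 of 341 fully
differentiating CpGs to classify an independent 100-sample validation
cohort perfectly. Every table lands under `results/`.

The same run is available as one call:

```r
library(methylforge)
res <- run_pipeline(default_config(seed = 1))
```

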