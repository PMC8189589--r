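---
title: "Methods: cross-modal covariation analysis with planted ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-modal covariation analysis with planted ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures `crossmode` implements,
the assumptions behind them, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where the methodology left room.

## The model

Each scan contributes two voxel maps: a striatal receptor-availability
map (ROI mask, order 10^3 voxels at full scale) and a brain-wide blood
flow map (order 10^5 voxels). Both are positive quantities; global
effects (injected dose, global perfusion) are removed by dividing every
voxel by the within-mask mean, so only spatial pattern remains. Stacking
scans gives two matrices `P` (scans × ROI voxels) and `C` (scans ×
brain voxels).

Because voxels vastly outnumber scans, each block is reduced by PCA
(columns standardized first — PCA is scale-sensitive) before CCA. CCA
finds weight vectors `U`, `V` over the K principal-component scores
maximizing `cor(PU, CV)`; the projected score pairs are the canonical
variates, and a pair of variates is a mode of covariation. Since CCA
maximizes correlation by construction, in-sample `r` is biased and all
inference is out-of-sample.

### Cross-validated mode test

For each `K` in `K_set` (default 2..10, averaged rather than selected,
to avoid tuning the dimensionality), the scans are split `n_splits`
times into 80% training / 20% test. Standardization, PCA and CCA are
fit on training rows only and applied frozen to the test rows; the test
statistic is the mean test-set correlation of the first canonical pair,
averaged over splits and then over `K`. The null rebuilds the identical
statistic after permuting the assignment of one modality's scans,
yielding `p = (1 + #{null ≥ observed}) / (1 + n_perm)` (the add-one
estimator, which can never return 0).

Repeated measures are the main threat to validity: most subjects
contribute a placebo and a drug scan, so scans are not exchangeable as
individuals. Two defenses are implemented, selectable independently:

* **Exchangeability-block permutation** (`scheme_kind = "block"`):
  paired subjects' two scans move as a unit (within-block order — the
  placebo/drug slotting — preserved), and only blocks of equal size
  exchange; singletons permute among themselves. For 3 paired + 2
  single subjects this gives exactly 3!·2! = 12 distinct permutations.
  The dependency inflates observed and null statistics equally, leaving
  `p` valid.
* **Pair-preserving splits** (`pair_preserving_split = TRUE`): both
  scans of a subject land on the same side of every train/test split,
  removing the train-test leakage entirely (at some cost in effective
  test-set variety).

The statistic is deliberately cheap per evaluation (Gram-matrix PCA on
the training rows, Cholesky-whitened first canonical pair), and a
compiled RcppArmadillo kernel evaluates it; a pure-R reference engine
computes the identical quantity and the test suite asserts agreement to
1e-12. Permutation loops at calibration scale (hundreds of cohorts ×
hundreds of permutations) are routine territory for compiled kernels in
neuroimaging statistics packages.

### Matching test

A complementary, more interpretable statistic: leave out two scans, fit
the whole stack on the rest, score the two held-out scans in both
modalities, and count success when the two striatal scores rank the
scans the same way as the two CBF scores. Ties are counted as failures
(conservative and deterministic). Chance is 50%.

One property of this statistic is worth stating because it constrains
what accuracies are attainable: if the two modalities' scores for a
random scan pair are bivariate normal with correlation ρ, the expected
matching accuracy is `1/2 + asin(ρ)/π` — 0.75 at ρ = 0.71, 0.856 at
ρ = 0.9, and 0.90 only at ρ ≥ 0.951. Even oracle scores cannot beat
this ceiling, so matching accuracy should always be read jointly with
the attained out-of-sample correlation.

### Covariation influence

The per-voxel Pearson correlation between the voxel's data and its
modality's canonical variate. This is a correlation, not a weight: it
is well-defined for voxels outside the PCA span, lives in [−1, 1], and
flips sign coherently with the (arbitrary) sign of the mode. Constant
voxels get influence 0 by convention.

### Drug challenge

Within-subject drug-minus-placebo differences of the two canonical
scores are Spearman-correlated (ranks are robust to outliers; ties get
average ranks; two-sided p). Because differencing removes per-subject
constants, the analysis is invariant to subject-level offsets. A
placebo-trained variant fits standardization, PCA and CCA on placebo
scans only and scores both sessions with frozen parameters, removing
the circularity of correlating a model with changes it partly saw.
Subjective drug-effect scores (10 items, 1–5 scale, summed) are
correlated with each scan's mean canonical score; the canonical sign is
arbitrary, so the sign of this correlation is only interpretable within
a fitted mode.

### Spatial surrogate nulls

Tests that compare a map against labeled regions (or against gene
expression) must respect spatial autocorrelation: free permutation of
voxels produces overly liberal nulls. Surrogates are built by
variogram matching:

1. Permute the target's values (destroying structure, keeping the
   marginal distribution).
2. Smooth with an isotropic exponential kernel at each scale in a
   geometric ladder (default: half the minimum neighbor distance up to
   3× the maximum pairwise distance, 15 rungs — the top rungs are
   near-flat on purpose, because rank-remapping restores roughness).
3. Fit amplitude and white-noise offset to the target variogram by
   nonnegative least squares on the semivariances, weighted by inverse
   squared target semivariance (relative error, so short lags are not
   drowned out by large far-lag semivariances).
4. Judge each scale by the realized surrogate — including the rank
   remap onto the target's sorted values — and run a second
   gain-correction pass that refits against a gain-adjusted target to
   compensate the slight roughening remapping introduces.
5. Choose the smallest scale whose error is within a tolerance factor
   (default 1.5) of the best: a parsimony tie-break that only matters
   when scales are statistically indistinguishable, as they are for
   unstructured targets.

Rank-remapping makes surrogates share the target's exact value
multiset, so any statistic that depends only on the value set (e.g. the
whole-map mean) is invariant and its test degenerates to p = 1, as it
should. On smooth synthetic fields (500 voxels, 10 mm correlation
length) the surrogate ensemble's mean variogram stays within ~15% of
the target at all bins and essentially always beats plain permutation.
The variogram uses Euclidean mm distance, 10 equal-width bins up to the
25th percentile of pairwise distances by default; empty bins are
dropped. These are engineering defaults, exposed as arguments.

An earlier design following the common k-nearest-neighbor recipe
(weights `exp(−d/d_k)` truncated at the k-th neighbor) was measured and
rejected: the truncation leaves membership discontinuities whose
short-lag roughness cannot reproduce strongly autocorrelated targets
(mean variogram errors of 2–3× at short lags).

### Gene expression and PLS

Expression preparation follows the standard spatial-transcriptomics
chain, each step its own function: probes must exceed background in at
least 50% of samples (at-threshold probes are kept — the removal set is
read as strictly-below); genes with several probes keep the probe with
the highest differential stability (mean over donor pairs of the
correlation of the probe's profile across locations sampled by both
donors; ties by probe id); samples match their nearest mask voxel
within 3 mm or are dropped; normalization is a scaled robust sigmoid
`1/(1 + exp(−(x − median)/(IQR/1.35)))` rescaled to [0, 1], applied
per donor. The 1.35 constant makes the IQR-based scale consistent with
the SD under normality. The normalization axis is configurable; the
default normalizes each gene across a donor's samples, which is what
makes genes comparable when donors are aggregated — the alternative
(each sample across genes) is available via `axis = "sample"` since the
methodological descriptions in this literature are ambiguous between
the two.

PLS regression (NIPALS; for a univariate response the inner loop is a
single exact pass per component) predicts covariation influence at the
matched voxels from the standardized expression matrix. Predictor
standardization is on by default because VIP is scale-sensitive.
Accuracy is the out-of-fold correlation between predicted and observed
influence, averaged over five repeats of five-fold cross-validation and
over component counts 2..10 (mean, not max — mirroring the CCA choice
of averaging over the hyperparameter). Significance uses permuted
responses and, more stringently, surrogate influence maps evaluated at
the same voxels. Gene importance is VIP,
`VIP_j = sqrt(p · Σ_k SS_k (w_jk)^2 / Σ_k SS_k)` with unit-norm weight
vectors, whose squares average to 1 across genes by construction; genes
are ranked by `z = mean bootstrap VIP / bootstrap SE` over resamples of
the samples (default model: 6 components, the out-of-sample optimum in
this analysis family; degenerate resamples with constant response are
redrawn and logged; ties break by gene id).

### Enrichment

For a gene set, the statistic is the absolute distance of the set
members' median rank from the list center, `|median(rank) − (n+1)/2|`
(midpoint convention for even counts; members missing from the list are
ignored but counted). The null draws random same-size sets from the
same ranked list without replacement; p is the add-one fraction of null
distances at least as large. The absolute distance makes the test
symmetric under list reversal, i.e. it detects enrichment toward either
end. Random sets are drawn from the list being tested (after any
brain-expressed subsetting), keeping the null conditional on the actual
universe.

## The synthetic cohort

`generate_paired_cohort()` emulates the study design: 23 paired
subjects (one placebo, one drug scan) plus 5 single-scan subjects — 51
scans. Which condition a single-scan subject received is not a
documented quantity in this design, so it is randomized rather than
asserted.

Each scan has a latent score `z ~ N(0,1)` plus `drug_shift` (default 1)
for drug scans. Each modality's side score is
`s = sqrt(rho)·z + sqrt((1−rho)·var(z))·eta`, so the two side scores
correlate at exactly `planted_rho` — including under nonzero drug
shift, whose variance contribution is folded into the noise scaling.
Maps are `exp(0.1 · (s·a + noise))` with `a` a smooth unit-norm
loading (8 mm correlation length) and spatially smooth noise (6 mm,
amplitude `noise_sd` = 0.2 by default) *orthogonalized against the
loading*, so the modal projection carries exactly the side score and
the planted correlation is exact rather than asymptotic. The
exponential keeps maps strictly positive (as BP_ND and CBF are) while
staying near-linear at this scale.

Expression samples (default 153, matching the study's eligible-sample
count) sit at ROI voxel centers, a fraction jittered by up to 2 mm to
exercise nearest-voxel matching; six donors; signal genes are
`effect_beta · loading + noise`, other genes pure noise; the probe
table plants a faithful first probe and noisier extras, with a random
subset flagged as sub-background. One gene set is built to overlap the
signal genes (default 60%), the rest are random.

What the generator does *not* emulate — and therefore what passing
tests do and do not show: no tracer kinetics or MRI physics, no
registration error, no inter-regional covariance structure beyond the
single planted mode, no donor batch effects, Gaussian (post-log) noise
only. Green tests demonstrate that the *procedures* are correct,
calibrated and powerful under their own assumptions, not that the
biological findings replicate.

## Problem sizes and defaults

The default pipeline configuration exercises everything end-to-end at
reduced scale — 51 scans, 150 ROI / 400 brain voxels, 30 splits over
K ∈ {2..10}, 200 permutations, 100 surrogates, 500 VIP bootstraps, 400
genes — and completes in about a minute on one CPU; these sizes are the
package's demo-scale choice and every count is a config field. The test
suite uses the same generator at sizes chosen per test (e.g. 200
cohorts × 100 permutations for type-I calibration of the mode test, at
60/120 voxels and 25 scans, since calibration validity does not depend
on problem size).

## Numerical choices and degenerate inputs

* Zero-variance columns standardize to 0 with SD treated as 1 (masked
  data can contain constant voxels).
* PCA components are sign-fixed (largest-magnitude loading positive)
  for cross-platform reproducibility; CCA fixes the sign so the
  in-sample canonical correlation is nonnegative.
* Rank-deficient CCA inputs (collinear score columns) raise an error
  rather than silently regularizing.
* All permutation p-values use the add-one estimator.
* Constant variates, constant subjective scales, empty networks, empty
  gene sets, nonpositive proton-density voxels: errors naming the
  offending object, not NaN propagation.
* In the two-sided network-overlap test, null-vs-observed comparisons
  use a 1e-8 relative tolerance so exact ties (rank-remapped
  whole-map statistics) are counted as ties regardless of summation
  order.
* One master seed drives every stage through derived per-stage streams;
  reruns with the same config are bit-identical, and the result bundle
  is stamped with the seed and a config hash.

## Known limitations

* Only the first canonical mode is fitted and tested; further modes
  would need deflation and their own inference.
* The exchangeability-block scheme supports subjects with one or two
  scans (the repeated-measures structure of this design), not general
  block sizes.
* Surrogate quality degrades for targets whose autocorrelation the
  exponential-kernel family cannot express (e.g. strong anisotropy);
  the variogram fit error is returned per surrogate so this is
  observable.
* The matching-accuracy ceiling `1/2 + asin(ρ)/π` means accuracies
  above ~86% are unreachable at ρ = 0.9 no matter how good the
  estimator; claims about matching should be calibrated against it.
* NIfTI I/O assumes lattice coordinates on a regular grid with a
  diagonal affine; it is meant for the package's own round trips, not
  as a general neuroimaging I/O layer.
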