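---
title: "Predicting and subtyping severe post-stroke aphasia from ordinal brain morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and subtyping severe post-stroke aphasia from ordinal brain morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

About a third of stroke survivors develop aphasia, and identifying early who
will remain severely impaired (Western Aphasia Battery aphasia quotient,
WAB-AQ, at or below 50) matters for allocating rehabilitation resources.
Lesion size and location explain much of the variance in severity, but tissue
integrity *beyond* the lesion — regional atrophy in the perilesional and even
contralateral cortex — carries additional signal. Crucially, that signal can
live in the *spatial arrangement* of atrophy rather than its total amount:
two brains with identical lesions and identical total gray-matter loss can
differ in whether that loss is focal or dispersed. Mass-univariate models and
classifiers on flattened voxel vectors are blind to this distinction; a 3D
convolutional network is not.

`aphasiamorph` implements this comparison end to end on ordinal morphometry
volumes — 3D grids coding background (0), CSF (1), gray matter (2), white
matter (3) and lesion (4), scaled to [-1, 1]:

1. a **synthetic cohort generator** with planted, total-matched spatial
   atrophy motifs and a WAB-AQ-like outcome;
2. deterministic **volume operations** (lesion merging, enantiomorphic
   healing, modal downsampling, common cropping, ordinal scaling);
3. a preallocated, repeated, nested, **stratified cross-validation plan**
   shared by all models;
4. a **3D VGG-family CNN** (native implementation with RcppArmadillo
   convolution kernels) and class-weighted **SVMs** with PCA/ICA reduction
   folded into cross-validation;
5. **fusion** by probability averaging and regularized-LDA stacking;
6. **saliency** by Grad-CAM++, DeepLIFT-style deep SHAP and
   kernel SHAP with conditional k-NN imputation;
7. **subtyping** by consensus clustering of saliency maps (eta-squared
   k-means, dip-test screening, PAC model-order selection, affinity
   propagation with exemplars); and
8. **evaluation**: concatenated-fold metrics, permutation testing, paired
   comparisons, and topic-map decoding of exemplar saliency.

## The synthetic cohort: what it emulates and what it does not

Real mode consumes pre-registered NIfTI tissue + lesion volumes and a
phenotype table. Synthetic mode makes every downstream stage testable
without clinical data. The generator emulates:

- **Geometry.** A deterministic, mirror-symmetric tissue template (WM core,
  GM shell, CSF at ventricles and margin) on a coarse grid (default
  24 x 28 x 24 at a nominal 8 mm). Randomness enters only through lesions,
  atrophy and outcomes, which isolates the stochastic components for tests.
- **Lesions.** Connected left-hemisphere masks grown by Eden growth
  (6-connectivity) from a lateral fronto-temporal anchor, mimicking the
  middle-cerebral-artery territory bias of aphasia-causing strokes; sizes
  uniform over a configurable range.
- **Atrophy motifs.** Exactly `atrophy_voxels` GM voxels are converted to
  CSF per subject. The *clustered* motif converts the neighbourhood of a
  random GM center; the *dispersed* motif scatters conversions uniformly
  over GM (including contralateral cortex, so extralesional signal exists).
  Totals are matched across motifs by construction — only the arrangement
  differs, which is precisely the signal a voxel-blind linear model cannot
  see.
- **Outcome.** `wab_aq = clip(100 - a*lesion_fraction - b*harmful_motif +
  N(0, sigma), 0, 100)`, binned at 25/50/75 into the four severity
  categories; severe = wab_aq <= 50. The defaults `a = 290, b = 25,
  sigma = 8` were calibrated once against the default grid and lesion sizes
  so that the simulated severe fraction sits near the 35% prevalence the
  classifiers are designed around, with all four categories represented;
  they were then frozen.
- **Reproducibility.** Each subject draws from an RNG stream derived from
  `(seed, subject index)`, so cohorts are byte-identical given a config and
  safe to parallelise.

It deliberately does **not** emulate MRI contrast, scanner noise,
registration error, tissue-segmentation failures, or realistic atrophy
topography. Passing the synthetic recovery tests therefore demonstrates that
the *pipeline machinery* behaves as specified (the CNN can exploit spatial
arrangement; consensus clustering recovers planted structure), not that any
particular accuracy will be attained on clinical data.

## Preprocessing choices

- **Lesion supersedes tissue** when maps are merged (code 4 wins).
- **Enantiomorphic healing** replaces tissue inside the lesion mask, dilated
  by `smooth_radius` voxels (26-connectivity), with the value at the
  midsagittal mirror position. On a symmetric template this restores the
  pre-lesion volume exactly, which the tests exploit as an oracle.
- **Downsampling** uses modal pooling over `factor^3` blocks. The mode is
  the natural ordinal-preserving reduction (interpolation would invent
  intermediate tissue codes); ties break toward the *larger* code
  (lesion > WM > GM > CSF > background) so rare, clinically salient classes
  survive pooling. Partial edge blocks use the voxels available.
- **Common cropping** removes planes that are background in *every* subject;
  one crop box is applied to all.
- **Scaling** is the fixed affine map `code/2 - 1`; no data-dependent
  statistics, so it cannot leak across folds.
- The **midline** lies between columns `d1/2` and `d1/2 + 1` of the
  left/right axis; grids are generated with an even first axis.

## The cross-validation plan

All models consume one immutable `partition_plan` (assert with
`object_hash()`): 20 repeats of 6 outer folds, 8 inner tuning folds, and a
stratified 70/30 train/validation resplit of each outer training set for CNN
early stopping. Stratification uses the four granular severity categories:
within each stratum, members are shuffled and dealt in equal quotas, with
remainders placed on the currently smallest folds. This guarantees both the
per-stratum <=1 imbalance and overall fold sizes within one subject
(231 subjects give test folds of 38-39; training sets of 192-193 give inner
held-out folds of 24-25 and validation sets of 58). Repeat `r` draws from
seed `seed + r`. Strata too small to split (one member in an outer training
set) are pooled into the modal stratum for the 70/30 resplit only; no
subject is ever dropped.

## The CNN engine

No deep-learning framework is attached: the package ships a compact 3D CNN
engine whose convolutions run as im2col + BLAS products in C++
(RcppArmadillo), with exact analytic gradients (verified against central
differences to ~1e-9 relative error in the test suite).

- **Architecture family.** 3x3x3 "same" convolutions with ReLU, 2x2x2
  ceil-mode max pooling after each block, and three terminal FC layers whose
  widths derive from the last block: FC1 doubles its channels, FC2 halves
  back, FC3 maps to the two classes. Batch normalization follows FC1 with
  dropout immediately after. Four frozen complexity levels span 4-5 blocks
  with 8-128 channels (`architecture_spec()`); the exact four variants are a
  package choice within that family, and explicit `blocks` remain
  configurable (down to 2 blocks for desk-scale work).
- **Training.** Class-weighted softmax cross-entropy (weights `N/(2 n_c)`),
  L2 penalty, SGD with momentum 0.9 under cosine annealing with warm
  restarts (first cycle 50 epochs, length doubling, floor 1e-10), 800
  epochs, mini-batches of 128 (full batch when the training set is smaller).
  The optimizer itself is a package decision recorded in `train_config()` —
  only the scheduler is prescribed by the protocol — and early stopping
  monitors the validation weighted loss with patience 100, restoring the
  best weights.
- **Tuning.** Grid search over complexity x dropout {0.6, 0.7, 0.8} x
  L2 {0.001, 0.01} x learning rate {0.1e-4, 0.8e-4, 1e-4}, scored by the
  smallest mean inner-fold validation loss; ties break to lower complexity,
  then lower learning rate.

## SVMs and reduction

`train_svm()` wraps the SMO-family solver in `e1071::svm` with per-class
costs multiplied by inverse class frequencies. The radial kernel uses
`gamma = 1/kernel_scale^2`, so `kernel_scale` plays the conventional width
role with its [1e-3, 1e3] search range; cost spans [1e-3, 2e4]; both are
drawn from 300 logarithmically spaced bins by random search (default 300
draws, configurable), scored by class-weighted hinge loss on inner folds.
Kernels are never tuned — separate linear and RBF models are trained.
PCA keeps the top-k components of the centered training table; ICA applies a
FastICA rotation (deflation, tanh contrast, seed-controlled) to the whitened
components, matching the "ICA on the components" construction. Projectors
and the Platt probability calibration are fitted on training rows only; a
poisoning test (sentinel values in held-out rows) pins the absence of
leakage. Degenerate calibrations fall back to clipped class frequencies.

## Fusion

Probability averaging sweeps `w` over 101 values in [0, 1] (F1 as a function
of `w` is piecewise constant, so this grid finds its exact maximum);
regularized-LDA stacking trains on a random stratified half of each outer
test fold using the two-feature input `(p_cnn, p_svm)` with
`Sigma_gamma = (1-gamma) Sigma + gamma diag(Sigma)` swept over 500 linearly
spaced `gamma` values, and predicts the other half. Both sweeps report
best-case values explicitly as optimistic bounds. The stacker is a
closed-form two-class Gaussian discriminant; at `gamma = 0` it reproduces
classical LDA (checked against `MASS::lda` and the closed-form pooled
discriminant).

## Saliency

- **Grad-CAM++** uses the closed-form second-order weighting for an
  exponential score target, `alpha = g^2 / (2 g^2 + sum(A) g^3)` with
  `g` the gradient of the class score w.r.t. the last block's feature maps,
  rather than numerical third derivatives — the numerically stable form of
  the original algorithm. A GAP-linear-head oracle (where the map must be
  proportional to the class-activation map, cosine > 0.99) pins
  correctness. Maps are trilinearly upsampled to the input grid.
- **Deep SHAP** is implemented as DeepLIFT rescale-rule multipliers averaged
  over a training background set: linear layers propagate multipliers like
  gradients, ReLUs rescale by delta-out/delta-in, and max pooling routes to
  the argmax of the explained input's forward pass. Completeness
  (attributions summing to the score difference) is exact for linear and
  pooling-free ReLU networks — both tested — and approximate across pooling
  layers, where argmax positions can differ between input and baseline.
- **Kernel SHAP** estimates Shapley values by Monte-Carlo permutation
  sampling with absent features imputed from the k nearest neighbours of the
  explained sample (k = 10% of the reference set, the conditional-kernel
  convention); an exhaustive-coalition oracle on small models pins the
  estimator.
- Maps are **rectified** (negatives zeroed) and **normalized to sum 1**;
  ROI analyses then read off the proportion of importance inside the lesion,
  a perilesional shell (default dilation 2 voxels = 16 mm at 8 mm
  resolution, 26-connectivity, a package default exposed as configuration),
  the extralesional left hemisphere, and their right-hemisphere homologs,
  with two-sample t-tests between predicted groups. Saliency is computed
  from the mean-performing repeat (F1 closest to the across-repeat mean,
  ties to the earlier repeat), restricted to correctly predicted subjects.

## Subtyping

Consensus clustering over voxel subsamples: 60% of voxels drawn 1000 times,
each subsample clustered for every k in 3-30 by k-means++ with 250 restarts
under the `1 - eta2` distance; the consensus matrix records co-clustering
proportions (every pair appears in every subsample because subsampling is
over features). Numerical choices worth stating:

- The eta-squared numerator equals `0.5 ||a - b||^2`, so member-mean
  centroids are a principled surrogate under Lloyd iterations; descent is
  nonetheless not guaranteed under the varying denominator, so iterations
  cap at 100 with best-so-far tracking, and empty clusters re-seed from the
  farthest point. The denominator algebra also bounds the coefficient to
  [0, 1].
- **Dip screening.** Solutions whose consensus distribution fails to reject
  unimodality (no consensus structure) are excluded. The dip statistic is
  computed by the greatest-convex-minorant / least-concave-majorant
  algorithm (validated against hand-solved small samples: dip of two
  separated atoms = 1/4, of three equally spaced points = 1/6, lower bound
  `1/(2n)`), with p-values by Monte-Carlo simulation under the uniform null
  (the dip is location/scale invariant).
- **PAC** counts consensus entries strictly inside (0.1, 0.9); solutions
  need PAC <= 0.1 (conventional bounds, exposed as configuration). Among
  surviving solutions the most complex (largest k) is selected; if none
  survive, the minimal-PAC k is returned with a warning.
- **Affinity propagation** (damping 0.7, preference initialised at the
  median similarity) extracts clusters from the selected consensus matrix,
  with the shared preference bisected until the cluster count matches the
  selected k (bounded iterations, nearest achievable otherwise); exemplars
  are refined to the member maximizing within-cluster similarity. Severe and
  nonsevere predictions are clustered in separate calls.

## Evaluation

Metrics are computed from predictions concatenated across outer folds:
precision, recall (= severe-class accuracy), nonsevere accuracy, balanced
accuracy, and F1 (0 when no positive predictions; at 35% prevalence the
always-severe baseline scores 0.52 and the always-majority baseline 0).
Permutation tests rerun the full model-building procedure on permuted labels
with partitions rebuilt per permutation and report
`p = (#{null >= observed} + 1)/(m + 1)`; permutation runs may use a reduced
configuration for tractability, recorded by the caller. Paired model
comparisons across repeats use the paired t-test with
`Cohen's d = mean(diff)/sd(diff)`. Topic decoding correlates lesion-masked
saliency with user-supplied topic maps and retains topics with `r > 0.2` and
Bonferroni-corrected `p < 1e-4`; the correlation test uses the
t-approximation with n = in-mask voxels, which ignores spatial
autocorrelation — decoding output is descriptive, not inferential.

## Problem sizes used by the test suite

The shipped tests run the full machinery at desk scale, chosen so each stage
still exercises its contract: spatial-sensitivity recovery uses cohorts of
200 subjects on 16^3 grids with 60 atrophied voxels, a 2-block CNN
(1x8, 1x16 channels) trained 150 epochs at lr 1e-3 with batch 16, against a
linear SVM, over 3 seeds; subtype recovery uses 90 maps from 3 archetypes
with k searched over 3-8, 50 voxel subsamples and 5 k-means restarts;
the end-to-end smoke experiment uses 36 subjects on 12^3 grids with 2
repeats of 2x2 nested folds. Study-scale defaults (20 repeats, 6x8 folds,
800 epochs, 1000 subsamples, 250 restarts, k up to 30) remain the exported
defaults.

## Design decisions that were genuinely open

- **Orchestration interface.** This is an analysis package driven from R:
  the exported functions plus `run_experiment()` are the interface, and
  stage outputs are cached as RDS keyed by a configuration hash in the run's
  output directory (single-level caching; deterministic recompute makes
  finer-grained caching unnecessary at package scale).
- **Real-data path.** Registration, bias correction and tissue segmentation
  of raw scans are out of scope; the volume operations apply to any
  pre-registered NIfTI inputs.
- **Stratified choices.** Whether the 70/30 resplit and the stacking
  half-split were stratified is not prescribed; both are stratified here to
  stabilise small-fold class composition.

## Known limitations

- The CNN engine is CPU-bound and single-process; study-scale training
  (20 repeats x 6 folds x full grids) is cluster-scale work by design.
- Deep SHAP completeness is approximate across max-pooling layers.
- Kernel SHAP at voxel resolution is Monte-Carlo expensive; it is intended
  for feature tables and small grids.
- The dip p-value is simulation-based; at the default 200 draws its
  resolution is 1/201.
- Synthetic cohorts cannot certify clinical performance; they certify the
  machinery.
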