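---
title: "Spanning-tree enhancement of connectivity matrices: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spanning-tree enhancement of connectivity matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connstack)
```

## Overview

`connstack` classifies subjects from parcellated resting-state time series
by converting each subject's functional-connectivity matrix into a
3-channel image and training a convolutional classifier under stratified
k-fold cross-validation. The scientific idea being operationalized is that
autism-related group differences express themselves as *over-connectivity*
(edges stronger than in controls) and *under-connectivity* (edges weaker or
anti-correlated), and that a channel layout which explicitly surfaces the
extremal edges of each subject's connectivity graph — its maximum and
minimum spanning trees — makes those differences easier for a CNN to
exploit than the raw matrix alone.

This vignette records the models and the decisions behind every stage, what
the synthetic generator does and does not emulate, and therefore what a
green test suite does and does not establish.

## Connectivity estimation

Given `X` (T timepoints × N ROIs):

* **Correlation.** Pearson correlation per ROI pair; diagonal exactly 1;
  zero-variance columns are an error naming the ROI. Invariant to shifting
  and positively rescaling any column.
* **Covariance.** `estimator = "empirical"` is the unbiased (T−1) sample
  covariance — chosen so the documented examples are exact. The default is
  `estimator = "shrunk"`, Ledoit–Wolf shrinkage `(1−s)S + s·μI` with the
  standard oracle intensity; it is strictly positive definite even when
  T < N (CC200 has 200 ROIs while many scans have fewer volumes), which
  the tangent stage requires. The base matrix `S` of the shrinkage formula
  uses denominator T, matching the estimator's derivation; the difference
  from T−1 is absorbed by the shrinkage intensity and is irrelevant
  downstream (stacks are min–max normalized per subject).
* **Tangent.** The group reference `G` is the affine-invariant (Karcher)
  geometric mean of the training covariances, computed by the fixed-point
  iteration `G ← G^{1/2} exp(mean_i log(G^{-1/2} C_i G^{-1/2})) G^{1/2}`
  with convergence declared when the Frobenius norm of the mean-log term
  falls below `tol` (default 1e−8, max 200 iterations; non-convergence is
  an error reporting the residual). Subjects are embedded as
  `log(W C W')`, `W = G^{-1/2}`. The stationarity property (the embedded
  training set sums to ≈ 0) and the exact round trip
  `C = G^{1/2} exp(·) G^{1/2}` are both asserted in the tests.

**Leakage control.** Whether the tangent reference should be fitted per
cross-validation fold or on the whole cohort is genuinely open in the
source material. Fitting on everyone leaks group information into the test
folds, so `cohort_stacks(..., fit_idx = training_indices)` is the default
path used by `cross_validate` (via its `stack_fn` hook) and per-fold
fitting is what the pipeline does; full-cohort fitting remains available by
passing all indices.

## Graph enhancement

The connectivity matrix becomes a complete weighted graph on the N ROIs
(diagonal discarded). Kruskal's algorithm with union-find extracts the
minimum and maximum spanning trees; edges are sorted with ties broken by
lexicographic (i, j) so tree extraction is reproducible even with repeated
weights.

Two decisions here were open:

* **Signed weights.** Correlation and tangent matrices carry negative
  entries. Trees are computed on the *signed* values by default: the
  minimum spanning tree then collects the weakest/most anti-correlated
  links, which is the under-connectivity reading, and the maximum tree the
  strongest links. An `absolute = TRUE` switch ranks by magnitude instead,
  because the choice is defensible either way; tree layers always store the
  original signed weights, not the ranking values, and not binary masks —
  magnitude information is kept for the classifier.
* **The plain ("thirds") stack.** Splitting a matrix "into thirds" is
  ambiguous when N is not divisible by 3 (116, 161 and 200 are not). The
  implemented rule partitions *rows* into three contiguous bands with
  ceiling-first sizes (116 → 39/39/38), giving an exact reconstruction
  invariant: the three channels sum elementwise to the source matrix and no
  entry is nonzero in more than one channel. The rule is isolated behind
  the `strategy` interface so an alternative reading can be swapped in.

The enhanced stack is `[matrix | MaxST layer | MST layer]`; channel 1 is
the source matrix exactly, channels 2 and 3 each carry 2(N−1) symmetric
entries.

## Classification

* **Backbones.** The seven standard ImageNet architectures are registered
  as exact layer-by-layer shape arithmetic (`valid`: side →
  ⌊(side−k)/stride⌋+1; `same`: side → ⌈side/stride⌉), truncated before the
  fully connected layers. That reproduces the expected feature-map sides,
  e.g. VGG = ⌊side/32⌋ and ResNet = ⌈side/32⌉ (3 and 4 at side 116).
  Pretrained ImageNet weights cannot be bundled or downloaded in this
  package's offline target environment, so *numeric* feature extraction
  and training run on `TinyConv` — three blocks of 3×3 'same' convolution,
  ReLU and 2×2 max-pooling (8/16/32 filters, He-initialized from a seed) —
  implemented in R with full backpropagation (gradients are checked
  against finite differences in the tests). Requesting features from an
  ImageNet backbone raises an informative error rather than silently
  substituting; the architecture registry still answers all feature-
  geometry questions about them.
* **Input scaling.** Backbones expect image-range inputs, and the source
  material does not state a normalization. Each stack is mapped by one
  shared linear transform onto [0, 255] (preserving the relative order of
  all entries and invariant to rescaling the stack), then the backbone's
  canonical mode is applied ("tf": x/127.5 − 1; "caffe": subtract the
  ImageNet channel means). A constant stack is an error.
* **Head and schedule.** Flatten → dropout → single sigmoid unit with
  binary cross-entropy; parameter count is `prod(feature_shape) + 1`.
  Hyperparameters that the source leaves open are fixed at conventional
  transfer-learning values and exposed in `training_schedule()`: dropout
  0.5, phase-1 Adam at 1e−3, fine-tuning at 1e−5 (validated to be lower
  than phase 1), batch size 16, early stopping on validation loss with
  patience 10. "The model converges" is operationalized as that early
  stopping rule. Phase 1 never touches backbone weights (asserted
  bit-identical); phase 2, when enabled, unfreezes everything.
* **Cross-validation.** Stratified folds (seeded round-robin within each
  class; stratification is not stated in the source but stabilizes class
  balance), one fold reserved for test, one of the remaining folds rotated
  into the validation role (the 8/1/1 split at k = 10), the rest training.
  With k = 2 there is no fold left over and validation falls back to the
  training subjects. Accuracy is (TP+TN)/(TP+TN+FP+FN) per fold, averaged
  arithmetically; per-fold confusion counts are retained so degenerate
  majority-class collapse is visible in reports.

## The synthetic cohort: the world the tests live in

`simulate_cohort` draws each subject's rows i.i.d. from a zero-mean
multivariate Gaussian whose population correlation matrix is the group
target: a compound-symmetric baseline (off-diagonal `base_corr = 0.1`, a
realistic mild mean functional coupling) with planted case-group shifts of
`±effect` on disjoint edge sets (defaults: `min(10, N/4)` over- and as many
under-connected edges — 7 + 7 at the default 30 ROIs; effect 0.3; 100
subjects per group; T = 150, a typical resting-state scan length). Targets
that are not positive definite after planting are rejected (naming the
group) rather than silently projected — a badly specified target would
otherwise invalidate recovery tests; eigenvalues within numerical zero of
the boundary (> −1e−8) are clipped up.

The generator emulates exactly what the connectivity estimators consume —
second-order structure with group differences — and nothing else. It does
**not** emulate temporal autocorrelation, hemodynamics, scanner/site
heterogeneity, motion artifacts, age/IQ covariates, or class imbalance
(balanced groups by default, the cohort's class balance being unstated in
the source). Consequently a green recovery test establishes that the
pipeline *correctly propagates and detects planted covariance differences
at realistic SNR*; it does not establish clinical accuracy on real cohorts,
and the headline accuracies reported for the 871-subject ABIDE cohort with
pretrained networks are explicitly out of reach here (they would require
that cohort, ImageNet weights and long training).

## Numerical choices

* Symmetric eigendecompositions back all SPD operations (`log`, `exp`,
  inverse square root); matrices are re-symmetrized after every such
  operation to keep drift below the 1e−10 symmetry tolerance.
* Connectivity matrices are validated: correlation entries clipped to
  [−1, 1] only within 1e−10 of the boundary, covariance PSD within −1e−8.
* The geometric-mean iteration starts from the arithmetic mean; with one
  input it converges in one step to that input.
* All randomness (simulation, fold assignment, weight init, batching,
  dropout) flows from user-visible integer seeds through a private RNG
  stream that never perturbs the caller's `.Random.seed`; derived seeds
  stay below 2^31.
* Stacks persist via R's native serialization (`.rds`) rather than HDF5:
  the target environment ships no R HDF5 bindings, and RDS provides the
  two properties that matter — bit-exact round trip and self-describing
  metadata (atlas/method/strategy/subject id).

## Known limitations

* ImageNet backbones: geometry only (see above); `TinyConv` carries the
  entire training contract.
* The plain-thirds construction is one reading of an ambiguous recipe.
* Fine-tuning at desk scale trains for a handful of epochs; the property
  asserted (median accuracy after ≥ median before, over seeds) is the
  direction of the effect, not its published magnitude. The acceptance
  suite runs the fine-tuning comparison on the enhanced correlation
  stacks, 3 seeds, to stay inside a ~10-minute budget.
* `run_pipeline` caches simulated cohorts and non-tangent stacks by config
  fingerprint; tangent stacks are deliberately never cached across folds
  because the reference must be refitted per training fold.
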