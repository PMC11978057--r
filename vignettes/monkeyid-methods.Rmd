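---
title: "Methods: classical face recognition for individual monkey identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classical face recognition for individual monkey identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Biomedical facilities housing cynomolgus monkeys (*Macaca fascicularis*) in
group cages need to identify individual animals quickly and without
handling. Traditional identification — chest or thigh tattoos read after
capture, manual observation — is invasive, slow, and stressful for the
animals. `monkeyid` implements a complete classical face-recognition
pipeline for this task: face crops are preprocessed to a canonical
grayscale resolution, transformed by one of four feature extraction
schemes, classified by a tuned classifier suite, benchmarked with
stratified 10-fold cross-validation, and deployed against video through a
near-real-time layer that pools half a second of frames and takes a
temporal majority vote.

Face *detection* is deliberately out of scope: production systems use a
fine-tuned CNN detector, which is neither portable nor desk-testable. The
package instead defines a detector *contract* (`detect_faces()`), and
ships a fixture detector that replays ground-truth bounding boxes from a
JSON sidecar, so every downstream component is exercised deterministically.

## Preprocessing

Every extractor consumes a `gray_image` at one canonical resolution.

* **Grayscale** is the unweighted channel mean, rounded half-up. Half-up
  rather than R's round-half-to-even keeps the result platform-stable and
  matches the common imaging convention.
* **Resize** is bilinear with pixel-center alignment and edge clamping.
  Bilinear is smooth, cheap, testable against a double-loop oracle, and
  never leaves the input's intensity envelope.
* **Canonical resolution** defaults to 300 rows x 200 columns
  (`canonical_size()`). The upstream system states "300x200" without naming
  axes; we read it as portrait (face crops are taller than wide) but treat
  it as configuration — every function takes `target_h`/`target_w`
  arguments, nothing is hard-coded.
* **Video** is resampled to a nominal rate (default 10 frames/s) by
  nearest-previous selection on a regular tick grid. Frames are never
  interpolated: identification must only ever see real camera frames.

## Feature extraction

**Eigenfaces (`ef`).** PCA on mean-centered, column-vectorized crops.
At 300 x 200 the pixel space has 60,000 dimensions, so the fit uses the
snapshot method — the eigendecomposition of the n x n Gram matrix of the
(at most a few hundred) training images — rather than a 60,000-dimensional
covariance. Components are retained until the cumulative explained-variance
ratio reaches 90% (`variance_target = 0.90`); the retained count is the
*minimum* achieving the bound, and a component landing exactly on the
target is included. Features are projections onto the retained basis.

**LBP histograms (`lbph`).** Each interior pixel is coded by comparing its
8 neighbors (clockwise from top-left, bit b set when neighbor >= center)
against it; per-cell 256-bin code histograms over an 8 x 8 grid are
L1-normalized and concatenated (16,384 dims). The upstream description
fixes none of radius, neighborhood, grid, or comparison; the defaults here
are the classical radius-1/8-neighbor formulation with `>=`, all
configurable through `lbp_spec()`. Codes are computed only where the full
neighborhood exists — no padding artifacts. Because the code depends only
on the *order* of intensities, the histogram is exactly invariant under any
strictly increasing intensity remapping of a non-saturating image; this is
tested bit-for-bit.

**Keypoint descriptors + bag of visual words (`sift_bow`, `surf_bow`).**
No SIFT/SURF implementation exists in this R environment, so two
simplified analogues are provided behind the package's descriptor-extractor
contract:

* *sift-like*: keypoints are 8-neighborhood maxima of the absolute
  difference-of-Gaussians response over a fixed scale ladder
  (sigma = 1.6 * 2^(s/2), s = 0..4); descriptors are 4 x 4 spatial cells x 8
  orientation bins of gradient magnitude over a 16 x 16 patch (128 dims,
  L2-normalized with the classical 0.2 clipping).
* *surf-like*: keypoints are maxima of the scale-normalized
  determinant-of-Hessian response; descriptors are per-cell sums of
  first-derivative (Haar-like) responses, (sum dx, sum |dx|, sum dy,
  sum |dy|) over 4 x 4 cells (64 dims).

Rotation invariance is omitted: face crops arrive upright from the
detector. "Strongest" means largest detector response, ties broken by
(y, x) scan order; only the top 5 (sift-like) / top 3 (surf-like)
descriptors per image are retained, mirroring the upstream configuration.
Descriptors pooled over the *training* images are quantized by k-means
into a 200-word vocabulary; an image is encoded as the L1-normalized
histogram of nearest-centroid assignments of its descriptors (zero vector
when no keypoints exist). Keeping only 3-5 descriptors per image makes
these histograms extremely sparse — which is exactly why the
bag-of-words columns trail eigenfaces and LBP in every benchmark, here
and upstream.

## Classifiers

The suite is kNN, LDA, and SVM with linear, polynomial (degree 2 and 3),
and RBF kernels.

* **SVM** is implemented in-package (no SVM library exists in this
  environment): the binary soft-margin dual is solved with
  `quadprog::solve.QP` (a 1e-8 ridge keeps the kernel matrix positive
  definite), multiclass by one-vs-one. Per-class confidences — which the
  realtime voting table needs but margins do not provide — come from a
  Platt-style sigmoid fitted to each pair's training decision values with
  the usual prior-corrected targets, combined by averaging pairwise
  probabilities and renormalizing. Confidences are therefore well-defined,
  non-negative, and sum to 1, but are calibrated on training decisions
  only and should be read as vote weights, not probabilities.
* **LDA** uses `MASS::lda` in standard form, untuned. Two guards make it
  robust on image features: columns with (near-)zero overall or pooled
  within-class variance are dropped (the sphering step divides by within
  sd), and when features outnumber samples the data are first projected
  onto at most n - g principal directions — within-class scatter is
  singular in that regime.
* **kNN** uses Euclidean distance with per-class neighbor-vote fractions
  as confidence; distance ties break by sample index for determinism.

**Feature scaling.** `train_classifier()` centers features and divides by
a single global factor, the root mean per-feature training variance. Two
alternatives were measured and rejected: no scaling leaves eigenface
projections at raw pixel scale, pushing RBF squared distances far outside
the useful range of the declared gamma search space; per-feature
z-scoring equalizes all directions and amplifies near-noise components,
which collapsed LBP-histogram accuracy in measurement. The global factor
fixes the kernel scale while preserving relative feature weights. Train
statistics are stored on the model and applied at prediction.

**Hyperparameter search.** `bayes_optimize()` is a Gaussian-process
optimizer with expected-improvement acquisition: a seeded Latin-hypercube
initial design, a squared-exponential surrogate (length scale 0.3 on
unit-scaled coordinates, 1e-6 nugget), and EI maximized over a random
candidate set plus local perturbations of the incumbent. The search is
capped at `max_evals` objective evaluations (default 50, matching the
upstream budget), is deterministic per seed, scores a failing objective
point as -Inf and continues, and always returns the argmax over its
evaluation trace. Search spaces default to C in [1e-3, 1e3] (log), RBF
gamma in [1e-5, 10] (log), polynomial coef0 in [0, 10], kNN k in [1, 25];
all conventional, all configurable. The tuning objective is mean accuracy
over a stratified inner cross-validation split of the training fold
(5-fold by default), so test data never influence hyperparameters.

The polynomial kernel's inner-product scale is 1/mean ||z||^2 over the
training rows rather than 1/dim: it is stable across feature
dimensionalities and invariant under orthogonal reparametrizations of
feature space (relevant below).

## Cross-validation benchmarking

`cross_validate()` uses stratified fold assignment (class counts in real
cohorts range widely — 21 to 182 images per identity upstream — and
stratification stabilizes per-fold estimates). Per fold, all fitted
extractor state (eigenbasis, codebook) is fitted on the training indices
only; the fitted indices are recorded in an audit attached to the report.
Both the mean of fold accuracies and the pooled fraction correct are
reported; the comparison grid displays the pooled value. Per-class
precision is diagonal over column sum of the pooled confusion matrix;
classes never predicted are absent from the map rather than given a fake
value.

Two exactness-preserving optimizations keep the full grid tractable on
one CPU:

* The per-fold eigenface fit is computed from one precomputed linear Gram
  matrix of all images: centering and eigenvectors are taken from the
  training sub-Gram only, which is algebraically the snapshot PCA of the
  training images. A regression test asserts equality (up to component
  sign) with the direct per-fold fit.
* A fold-independent feature matrix with more columns than rows (LBP-H:
  16,384) is re-expressed in the orthonormal basis of its row span before
  classification. All inner products and Euclidean distances are preserved
  exactly, so every classifier in the suite — all of which depend on the
  features only through inner products or distances — is unchanged, while
  kernel computations drop from 16,384 to at most n dimensions.

`comparison_grid()` evaluates the extractor x classifier cross-product
under one shared fold assignment, reusing per-fold features across
classifiers; a failing cell is recorded and the grid completes.

## The realtime layer

A session advances a pooling window (default 0.5 s) across the resampled
stream at the update cadence (default 0.5 s, i.e. non-overlapping windows
that partition the timeline). Within a window, each frame is detected,
cropped, preprocessed to the *recognizer's* training resolution, and
classified; rows of per-class confidences form the window's confidence
table. Multiple simultaneous detections are linked across frames into
chains by box overlap (IoU >= 0.3 against the chain's last box), one table
per chain — group cages contain many animals, and pooling different
individuals into one vote would be meaningless.

`majority_vote()`: each row votes for its argmax (row ties to the
lexicographically first class); the window's identification is the modal
vote. Modal ties break by larger summed confidence across the tied
classes, then lexicographically — the upstream description says only
"most common outcome", so the tie rule is declared here and verified
against brute-force enumeration over all 3^5 argmax patterns of a
5-frame, 3-class table. Windows with fewer than `min_rows` rows (default
1) return `ABSTAIN`: an empty window must never fabricate an identity.

When a single identity is selected (the one-animal verification mode used
when confirming identities in a group cage), overlay events are emitted
only for windows predicted as that identity. Session logs are JSON lines,
one record per window x chain, and are byte-identical across replays of
the same stream, model, and seeds.

## The synthetic generator

No recordings are deposited upstream, so the package carries a
deterministic generator as a first-class module. Faces are procedurally
composed — ellipse head, two eye discs with glints, muzzle plate with
nostrils and mouth line, brow band, band-limited fur-noise texture — with
identity carried in *both* global geometry (which favours eigenfaces) and
texture statistics (which favours LBP histograms), so all four extractor
paths are exercised non-trivially. Identities are drawn by rejection
sampling to a minimum pairwise separation (default 0.25 in unit-scaled
parameter space).

Nuisance parameters and their defaults (`default_config_ranges()`) are
the generator's stated world: lighting gain 0.8-1.2 with a linear shading
ramp of slope up to ±0.15 (uncontrolled cage lighting), pose jitter up to
6 px translation and 5 degrees rotation (freely moving animals seen
nearly frontally), Gaussian blur sigma 0.5-1.2 px and sensor noise
sd = 8 on the 0-255 scale (consumer camera at cage distance). The render
pipeline is compose -> blur -> noise -> integer quantization -> lighting ->
clip; applying the lighting gain *after* quantization means a gain >= 1 on
a non-saturating render is a strictly increasing intensity map — the
transformation LBP is provably invariant to, which the tests exploit.
Rendered RGB channels are identical (the identity signal is achromatic);
grayscale conversion is still exercised end to end.

What a green test does *not* establish: the generator has no photorealism,
no 3-D pose (rotation is in-plane), no occlusion, no expression change, no
inter-individual similarity structure of real macaque faces. Benchmark
numbers on synthetic cohorts say the pipeline is correct and its ordering
of methods is as expected (holistic eigenfaces >= sparse bag-of-words), not
that any particular accuracy transfers to real animals.

## Numerical and degenerate-case conventions

* Eigen-fits drop eigenvalues below 1e-10 of the largest; an all-identical
  image set is a degenerate-data error.
* k-means (`stats::kmeans`, seeded) retries up to 5 deterministically
  derived seeds on empty-cluster failures; k = 1 and k = n(distinct) use
  closed forms.
* Nearest-centroid and argmax ties resolve to the lowest index; kNN
  distance ties to the lowest sample index.
* Boxes are 0-based, half-open; crops degenerate after clipping (< 2 px a
  side) are errors, clipping itself is a warning.
* All randomness flows from user-visible integer seeds through an internal
  RNG-state-preserving helper; sub-seeds stay below 2^31.

## Runtime scaling of the test suite

The acceptance benchmark reduces the *tuning budget* (6 evaluations over 3
inner folds per grid cell) and the noise-sweep uses 20 images per identity
— runtime knobs, never the generator's stated nuisance levels or the
acceptance thresholds. With these settings the full 4-extractor x
6-classifier, 10-fold grid on 8 x 60 images completes in about 7 minutes
on one CPU.

## Known limitations

* SVM confidence calibration uses training decisions (no held-out
  calibration split); confidences are slightly optimistic.
* The sift-like/surf-like extractors are not scale-space-exact SIFT/SURF;
  conclusions about those columns are qualitative (sparse local
  descriptors + tiny vocabularies underperform holistic features), which
  is the same qualitative conclusion reached upstream.
* LDA's confidence is a Gaussian posterior under equal-covariance
  assumptions that image features violate freely.
* The fixture detector replays ground truth; detection errors (missed
  faces, drifted boxes) are representable through edited sidecars but not
  modeled by default.
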