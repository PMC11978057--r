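# monkeyid

Individual identification of cynomolgus monkeys (*Macaca fascicularis*)
from face images, for research facilities that need to tell animals apart
in group housing without capture or invasive marking.

The package implements the classical face-recognition stack end to end:

* **Preprocessing** — grayscale by RGB channel averaging, bilinear resize
  to a canonical 300 x 200 crop, video resampling to 10 frames/s.
* **Feature extraction** — eigenfaces (PCA components retained to 90%
  cumulative explained variance, snapshot method), local binary pattern
  histograms (radius 1, 8 neighbors, 8 x 8 grid, 256 bins per cell),
  and sparse keypoint descriptors (SIFT-like difference-of-Gaussians,
  SURF-like determinant-of-Hessian; strongest 5 / 3 kept) encoded against
  a 200-word k-means bag-of-visual-words codebook.
* **Classification** — SVM (linear, polynomial degree 2/3, RBF kernels;
  one-vs-one dual solved with quadprog; Platt-calibrated per-class
  confidences), LDA, and kNN, with hyperparameters chosen by
  Gaussian-process Bayesian optimization (≤ 50 objective evaluations) on
  an inner cross-validation split.
* **Benchmarking** — stratified 10-fold cross-validation with leak-free
  per-fold extractor fitting, per-class precision, and the full
  extractor x classifier comparison grid written as CSV.
* **Realtime layer** — 0.5 s frame pooling, a frames x classes confidence
  table per tracked face, temporal majority voting with an explicit
  abstention rule, 0.5 s update cadence, and a single-selected-identity
  display mode for verifying one animal at a time in a group cage.
* **Synthetic generator** — a deterministic multi-identity face-image
  generator (procedural geometry + fur texture, controllable lighting,
  pose jitter, blur, and sensor noise) standing in for recordings that
  cannot be shipped, plus a fixture face detector replaying ground-truth
  boxes from a JSON sidecar.

In eigenface space, a crop `x` is represented by its projection
`f = B (x - mu)` onto the orthonormal basis `B` of leading principal
components of the training crops; `B` retains the smallest number of
components whose cumulative explained-variance ratio reaches 0.90. A
window of video frames is identified by the modal argmax of the per-frame
confidence vectors, with ties broken by summed confidence and then
lexicographic order.

## Worked example

```r
library(monkeyid)

# 1. a synthetic cohort standing in for undeposited recordings
pop <- make_population(n_identities = 4, seed = 7)
ds  <- synth_dataset(pop, images_per_id = 15, seed = 7)
print(ds)
#> <face_dataset: 60 images, 4 identities (15-15 images/id)>

# 2. fit a recognizer: eigenfaces + tuned SVM-RBF
rec <- face_recognizer(ds, extractor = "ef",
                       classifier = classifier_spec("svm", "rbf", max_evals = 8),
                       seed = 7)
summary(rec)
#> Face recognizer
#>   extractor : ef
#>     20 components, 90.4% cumulative variance
#>   classifier: svm_rbf
#>     tuned: C=2.051, gamma=0.236
#>   classes   : ID01, ID02, ID03, ID04
#>   n_train   : 60

# 3. benchmark honestly with stratified 10-fold cross-validation
rep <- cross_validate(ds, "ef", classifier_spec("svm", "rbf", max_evals = 8),
                      folds = 10, seed = 7, inner_folds = 3)
print(rep)
#> <cv_report: ef x svm_rbf, 10-fold>
#>   mean accuracy:   1.0000
#>   pooled accuracy: 1.0000
#>   fold range:      [1.0000, 1.0000]

# 4. a small comparison grid
grid <- comparison_grid(ds, extractors = c("ef", "lbph", "sift_bow"),
                        classifiers = list(classifier_spec("knn", max_evals = 6),
                                           classifier_spec("svm", "rbf", max_evals = 6)),
                        folds = 10, seed = 7, inner_folds = 3)
print(grid)
#> <cv_grid: 2 classifiers x 3 extractors, 10-fold, accuracy %>
#>          ef lbph sift_bow
#> knn     100  100    88.33
#> svm_rbf 100  100    98.33

# 5. realtime identification on a synthetic 6 s group-cage video
vid <- synth_video(pop[1:3], duration_s = 6, fps = 10, segment_s = 2, seed = 8)
session <- run_session(vid$stream, fixture_detector(vid$boxes), rec,
                       session_config(window = 0.5, update_interval = 0.5))
print(session)
#> <id_session: 13 window records, 13 overlays; predictions: ID01:4 ID02:5 ID03:4>
```

Reading the output: the eigenface model needed 20 components to cover 90%
of training variance; holistic features (eigenfaces, LBP histograms)
separate this easy 4-identity cohort perfectly under 10-fold
cross-validation, while the sparse 5-descriptor bag-of-words
representation trails — the same ordering the method comparison shows at
full scale. The session identified the one visible animal in each of the
thirteen 0.5 s windows, matching the 2 s segments in which each identity
appears.

Harder worlds (more identities, stronger noise, heavier pose jitter) are
one `default_config_ranges()` edit away; accuracy degrades monotonically
with sensor noise, which the test suite checks.

## Command line

```sh
Rscript exec/monkeyid synth     --identities 8 --images_per_id 60 --seed 1 --out_dir data/
Rscript exec/monkeyid benchmark --identities 8 --seed 1 --out_dir results/
Rscript exec/monkeyid identify  --identities 3 --duration_s 10 --selected_id ID02 --out_dir session/
```

Each run writes a provenance block (config, seed, versions) sufficient to
reproduce its outputs bit for bit.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main pipeline from scratch at the given seed: it
synthesizes an 8-identity face set, runs the eigenface + SVM-RBF 10-fold
cross-validation benchmark, replays a 10 s realtime identification session
on a synthetic 3-identity video, and writes the JSON report to `--out`.

## Package layout

* `R/imaging.R` — containers, preprocessing, stream resampling, file I/O
* `R/detect.R` — detector contract, fixture detector, crop semantics
* `R/features.R` — eigenfaces, LBP-H, keypoints, codebooks, BoW encoding
* `R/classify.R` — SVM/LDA/kNN, confidences, Bayesian optimization
* `R/recognizer.R` — the fitted-model interface (`face_recognizer()`)
* `R/evaluate.R` — stratified CV, precision, comparison grid
* `R/realtime.R` — pooling, confidence tables, voting, sessions
* `R/synth.R` — synthetic faces, datasets, videos
* `R/cli.R`, `exec/monkeyid` — the three phase commands
* `vignettes/monkeyid-methods.Rmd` — model assumptions, parameter
  rationale, numerical conventions, limitations
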