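# twinwave

Classification of two-class brain MRI slice cohorts — Alzheimer's disease
patients versus healthy controls — from dual-tree complex wavelet texture
features, with a from-scratch linear Twin Support Vector Machine and a
repeated stratified cross-validation protocol.  Everything runs on synthetic
brain phantoms, so the full pipeline is testable and reproducible without
access to clinical data.

## What it computes

Each subject is a stack of 2-D grayscale slices (PNG input, resized to a
256 × 256 working grid).  The pipeline is:

1. **DTCWT features.** A 2-D dual-tree complex wavelet transform
   (Q-shift filter banks, perfect reconstruction, six directional subbands
   per level at ±15°, ±45°, ±75°).  The subband *magnitudes* at the scale
   with 16 × 16 subbands are nearly shift invariant; per slice they give
   6·16·16 = 1536 features, i.e. 49,152 for a 32-slice subject.  A
   critically sampled DWT baseline is included for comparison.
2. **PCA + Fisher LDA.** SVD-based PCA to 20 scores (at most n − 1 carry
   variance), then the Fisher discriminant axis solving
   S_B W = λ S_w W via S_w⁻¹S_B with a small ridge — one projected feature
   for two classes.
3. **Twin SVM.** Two nonparallel hyperplanes, each solving
   min ½‖X₁w + b‖² + C 1ᵀξ  s.t.  −(X₂w + b) + ξ ≥ 1, ξ ≥ 0
   (and symmetrically), via the Lagrange dual box QP solved by a
   primal-dual interior-point method (KKT residual ≤ 1e−6).  A sample takes
   the class of the nearer plane.
4. **Evaluation.** Repeated stratified k-fold cross-validation with
   per-fold refitting of the whole model (leak-free); accuracy,
   sensitivity, specificity, precision, recall, F-measure and g-mean
   reported as mean ± sd over runs from pooled per-run confusion counts.

## Worked example

```r
library(twinwave)

spec   <- phantom_spec(image_size = 64, n_slices = 4, effect_size = 0.25,
                       noise_sd = 0.08, seed = 42)
cohort <- phantom_cohort(spec, n_patients = 20, n_controls = 20)
X      <- cohort_features(cohort)         # 40 x 6144 feature matrix
cv     <- cv_evaluate(X, k = 5, runs = 10, seed = 1)
summary(cv)
```

```
Cross-validated pipeline evaluation [DTCWT+PCA+LDA+TSVM]
  5-fold stratified CV, 10 run(s), seed 1

  accuracy      80.00 +/- 3.73 %
  sensitivity   80.50 +/- 4.97 %
  specificity   79.50 +/- 4.38 %
  precision     79.76 +/- 3.89 %
  recall        80.50 +/- 4.97 %
  f_measure     80.07 +/- 3.80 %
  gmean         79.95 +/- 3.71 %
```

A weak structural effect (`effect_size = 0.25`: slightly enlarged
ventricles, slightly thinned cortical band) under strong noise is recovered
at 80% accuracy; sensitivity and specificity are balanced because the folds
are stratified and the twin SVM treats the classes symmetrically.  With
`effect_size = 0` the same call hovers at chance level, and from
`effect_size ≈ 0.5` upward it saturates at 100%.  `cv$fold_accuracy` holds
the run × fold accuracy table, `predict(wave_classifier(X), newX)` classifies
new subjects, and `cohort_features(cohort, transform = "dwt")` or
`cv_evaluate(X, use_lda = FALSE)` switch in the DWT baseline or drop the
discriminant step.

## Command line

```sh
inst/scripts/twinwave synth    --out cohort --n-patients 20 --n-controls 20 --seed 1
inst/scripts/twinwave extract  --manifest cohort/manifest.tsv --out features.tsv
inst/scripts/twinwave evaluate --features features.tsv --out-dir results --k 5 --runs 10
```

Subcommands write PNG cohorts + manifest, feature TSVs with a JSON layout
sidecar, and the run × fold accuracy table plus JSON metric summary.

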