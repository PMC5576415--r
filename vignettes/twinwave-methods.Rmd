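---
title: "Methods: dual-tree complex wavelet features and twin SVM classification"
author: "twinwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-tree complex wavelet features and twin SVM classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinwave)
```

## The problem

Structural MRI of Alzheimer's patients shows morphometric change relative to
healthy controls — enlarged ventricles, cortical thinning, altered tissue
texture.  `twinwave` implements a slice-based classification pipeline for
such two-class cohorts: each subject contributes a stack of 2-D grayscale
slices, each slice is summarized by multiscale directional texture features,
and a discriminative classifier separates patients from controls under a
repeated, stratified cross-validation protocol.  The pipeline is

1. preprocessing: PNG slices, luminance, min-max normalization to $[0,1]$,
   bilinear resize to a $256 \times 256$ working grid;
2. feature extraction: magnitudes of dual-tree complex wavelet (DTCWT)
   directional subbands at one scale, concatenated across the slices of a
   subject;
3. dimensionality reduction: PCA to a small number of scores, then a Fisher
   linear discriminant projection to a single axis;
4. classification: a linear Twin Support Vector Machine (TSVM);
5. evaluation: repeated stratified $k$-fold cross-validation reporting
   accuracy, sensitivity, specificity, precision, recall, F-measure and
   g-mean as mean $\pm$ sd over runs.

Because clinical cohorts cannot ship with a package, a phantom generator
produces synthetic two-class cohorts with a controllable effect size; all
tests and the reproduction script run on phantoms.

## The dual-tree complex wavelet transform

A critically sampled 2-D DWT is shift variant — subband energy can change
substantially when the image moves by one pixel — and resolves only
horizontal/vertical structure.  The DTCWT runs two real wavelet trees per
axis whose outputs form the real ("h" tree) and imaginary ("g" tree) parts
of approximately analytic complex coefficients.  Writing the two tree
transforms as operators $D_h$ and $D_g$, the complex coefficients of an
image $x$ are $T_h + j\,T_g$ with $T_h = D_h x$, $T_g = D_g x$.  In 2-D the
four combinations of row/column trees yield, per level, six complex
directional subbands oriented near $\pm 15^\circ$, $\pm 45^\circ$ and
$\pm 75^\circ$; coefficient magnitudes are nearly invariant to small image
shifts, which is exactly the stability a texture feature wants.

Design choices:

* **Filters.** Level 1 uses the symmetric biorthogonal 9/7 pair; both trees
  share it, with the g-tree offset by one input sample.  Levels $\ge 2$ use
  a 14-tap orthonormal Q-shift lowpass whose group delay is $6.25$ samples;
  the h tree takes its time-reverse (delay $6.75$), keeping the two trees'
  sampling grids interleaved by half a sample at every scale.  Both filter
  sets were refined in-package by a Gauss–Newton pass on the exact
  perfect-reconstruction and Nyquist-zero constraints, so reconstruction is
  exact to machine precision and highpass subbands of a constant image
  vanish identically.  The filter bank is pluggable
  (`dtcwt_filters()`); every transform test is property-based (perfect
  reconstruction, linearity, shift invariance), so any analytic-pair choice
  passes.
* **Boundaries.** Periodic (circular) extension throughout.  With the
  decimated filter banks this gives *exact* inversion for both filter
  families with simple indexing, and it matches the circular-shift
  definition used by the shift-invariance statistic.  The cost — wrap-around
  edges become image content — is immaterial here because slices have dark
  borders far from tissue.
* **Tree pairing.** The tree that is delayed by one sample at level 1 must
  take the *smaller*-delay Q-shift filter at later levels; the opposite
  assignment cancels the offsets and destroys analyticity.  This is asserted
  by the shift-invariance tests (DTCWT score $< 0.05$ on edge images at
  level 3, versus typically $0.1$–$0.3$ for the critically sampled DWT).
* **Rejection, not padding.** Images whose sides are not divisible by
  $2^{\text{levels}}$ are rejected with a message naming the required padded
  size; preprocessing guarantees $256 \times 256$, so this only triggers on
  misuse.

## Features

At the default scale the six directional subbands of a $256\times256$ slice
are $16 \times 16$, giving $6 \cdot 16 \cdot 16 = 1536$ magnitudes per slice
and $1536 \times 32 = 49{,}152$ features for a 32-slice subject.  The scale
is defined *operationally* as "the level whose subbands are $16\times16$"
(level 4 for 256-pixel slices) because that is the layout the published
feature counts imply; the level index is configurable.  Magnitudes (moduli)
are used rather than real/imaginary parts: the modulus is the
shift-invariant quantity, and it reproduces the printed dimensions exactly.
Ordering is slice-major, then subband, then column-major within a subband,
recorded in a machine-readable `layout` attribute and JSON sidecar.  The DWT
baseline concatenates the approximation and three detail subbands at the
same scale ($4 \cdot 16 \cdot 16 = 1024$ per slice).  No per-feature
standardization is applied beyond the mean-centering inside PCA.

## PCA and the Fisher discriminant

With $n \sim 10^2$ subjects and $p \sim 5 \times 10^4$ features, PCA is
computed from the SVD of the centered data matrix (equivalent to the
covariance eigendecomposition, stable in the $p \gg n$ regime); at most
$n - 1$ components carry variance.  The default of 20 retained components
follows the published operating point; component signs are fixed by making
each component's largest-magnitude entry positive.

The Fisher step maximizes $J(w) = \frac{w^T S_B w}{w^T S_w w}$ with the
between-class scatter averaged over classes,
$S_B = \frac1c \sum_j (m_j - m)(m_j - m)^T$, and the within-class scatter
left unnormalized, $S_w = \sum_j \sum_{z \in j} (z - m_j)(z - m_j)^T$ —
any consistent rescaling leaves the eigenvectors unchanged.  The axes solve
$S_B W = \lambda S_w W$ via the eigenvectors of $S_w^{-1} S_B$.  $S_w$ must
be invertible for that route, which the pipeline guarantees by ordering PCA
before LDA and capping the retained components at $n - c$; a small ridge
$10^{-6}\,\mathrm{tr}(S_w)/d$ is added as the standard small-sample
safeguard (the price is that LDA is invariant to invertible
re-parameterizations only up to $\sim 10^{-3}$, which the tests document).
For two classes a single discriminant axis remains, so the twin SVM operates
on 1-D projected features when LDA is enabled.

## The twin SVM

The TSVM fits two nonparallel hyperplanes $(w_1, b_1)$, $(w_2, b_2)$, each
close to one class and pushed unit distance from the other.  With
$H = [X_1\;\mathbf 1]$, $G = [X_2\;\mathbf 1]$, plane 1 solves

$$\min_{u_1,\xi}\ \tfrac12\|H u_1\|^2 + C_1 \mathbf 1^T \xi
\quad\text{s.t.}\quad -G u_1 + \xi \ge \mathbf 1,\ \xi \ge 0,$$

and plane 2 the same program with the class roles swapped (a fully symmetric
convention: swapping the class labels swaps the planes exactly).  Each
primal is solved through its Lagrange dual, a box-constrained QP
$\max_\alpha \mathbf 1^T\alpha - \tfrac12 \alpha^T G (H^TH + \varepsilon
I)^{-1} G^T \alpha$, $0 \le \alpha \le C$, with
$u_1 = -(H^TH+\varepsilon I)^{-1}G^T\alpha$.  The relative ridge
$\varepsilon$ (default $10^{-6}$, scaled by $\mathrm{tr}/d$) is required
because $H^TH$ is rank deficient whenever features $\ge$ samples.

Numerics: when $\varepsilon$ is small the dual Gram matrix acquires
eigenvalues of order $1/\varepsilon$, and first-order solvers stall.  The
dual is therefore solved by a primal-dual interior-point method — whose
barrier term regularizes each Newton system, making the iteration count
essentially independent of conditioning — followed by an exact linear solve
on the free (strictly inside the box) multipliers.  The contract is a
projected-gradient KKT residual below $10^{-6}$ on the multiplier scale
(residual divided by $\max(1, C)$); fits record the achieved residual, and
the tests verify agreement with an independent generic-QP solve of the
primal to $10^{-4}$ relative error on small instances.  Prediction assigns
a sample to the class whose plane has smaller perpendicular distance
$|w_k^Tx + b_k|/\|w_k\|$, ties to class 1 (patients).  Default
$C_1 = C_2 = 1$; `twinsvm_grid_search()` offers exhaustive inner-CV
selection over a grid (ties toward smaller penalties), as the model itself
prescribes no values.

## Evaluation protocol

`make_cv_plan()` builds repeated stratified $k$-fold partitions: per-class
counts per fold differ from proportionality by at most one, and class
remainders go to the currently smallest folds so fold totals balance (95
subjects split 51/44 at $k = 5$ give five folds of 19 with 10–11 patients
each).  Within every fold the *entire* model — PCA, LDA, TSVM — is refitted
on the training folds only; feature extraction is per-subject and uses no
cross-subject information, so it is computed once.  This leak-free,
per-fold refitting is deliberately conservative: pipelines that fit the
projections on all data before cross-validating report optimistic numbers.
Per run, confusion counts are pooled over folds and the seven statistics —
accuracy, sensitivity, specificity, precision, recall ($\equiv$
sensitivity), F-measure, g-mean $=\sqrt{\text{sens}\cdot\text{spec}}$ —
computed from the pooled counts; the report is mean $\pm$ sd **over runs**
(10 by default), plus the run $\times$ fold accuracy table.  Ratios with
zero denominators are reported as `NA`, never raised.  All randomness flows
from one integer seed; identical seeds give bit-identical reports.

## The phantom generator

`phantom_cohort()` renders, per subject, a stack of slices through an
elliptical "brain": a bright cortical band carrying angular texture, an
interior with smooth low-frequency texture, and two dark elliptical
ventricles.  The patient class enlarges the ventricle axes by
$1 + 0.35\,\text{effect\_size}$ and thins the cortical band proportionally —
the atrophy-like morphometric difference the pipeline targets.  Per-subject
jitter ($\pm 3\%$ geometry, $\pm 5\%$ ventricle size) models anatomical
variability; a smooth through-stack scaling emulates slicing an ellipsoid;
additive Gaussian noise (sd 0.05 by default, intensity units) models
acquisition noise.  Defaults are $256 \times 256$ pixels and 32 slices per
subject — the working geometry of the pipeline.  Every subject derives its
own RNG stream from the master seed, so cohorts are reproducible bit-exactly
and patients/controls are exchangeable when `effect_size = 0`.

What the phantoms do *not* model: MRI physics (bias fields, partial-volume
effects, Rician noise), registration error, anatomical heterogeneity beyond
ellipse jitter, and 3-D continuity across subjects.  Passing tests therefore
demonstrate that the implementation is correct and that the pipeline
recovers a known structural effect under controlled conditions — not that
clinical accuracy figures transfer.

## Problem sizes used in tests and the reproduction script

Unit and property tests run on 32–128 pixel images and cohorts of 10–60
subjects with 1–4 slices; these sizes exercise every code path at full
numerical strictness.  The acceptance checks use: one full-size subject
(256 pixels, 32 slices) for the printed feature dimensions; 60-subject
phantom cohorts (30/30) for the null-calibration and effect-monotonicity
checks (64 pixels, 4 slices) and for the strongly separated cohort (256
pixels, 8 slices, effect 2, noise 0.03) on which all four pipeline variants
(DTCWT/DWT $\times$ LDA on/off) are evaluated with 5-fold CV.  The null
check asserts accuracy within the 95% binomial band around 0.5 at $n = 60$;
monotonicity in effect size is asserted with a 0.07 sampling tolerance.

## Known limitations

* Periodic boundary handling can leak wrap-around edges into features for
  images with bright borders; slices with dark margins (the intended input)
  are unaffected.
* The LDA ridge makes the discriminant axis very slightly
  parameterization-dependent.
* The TSVM is linear by design; kernel variants are out of scope.
* The phantom generator's simplifications listed above mean synthetic
  accuracies say nothing quantitative about clinical data.
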