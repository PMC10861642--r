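---
title: "Composite texture features for tumor-slice classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite texture features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumortexture)
```

## The problem and the representation

Classifying T1-weighted MRI brain-tumor slices (meningioma vs. glioma vs.
pituitary) is often approached with deep networks; an alternative is a
hand-crafted texture representation that a linear classifier can separate.
`tumortexture` builds one fixed-length descriptor per 2-D grayscale image
from two classical texture families and their fusion:

1. **GLCM block (5 values).** The gray-level co-occurrence matrix
   $P(i,j)$ counts how often gray levels $i$ and $j$ occur at pixel offset
   $(S, \theta)$, here $S = 1$ and
   $\theta \in \{0^\circ, 45^\circ, 90^\circ, 135^\circ\}$, symmetrized and
   normalized. From each $P$ we take contrast
   $\sum P(i,j)(i-j)^2$, dissimilarity $\sum P(i,j)\lvert i-j\rvert$,
   homogeneity $\sum P(i,j)/(1+\lvert i-j\rvert)$, energy
   $\sqrt{\sum P(i,j)^2}$ and correlation
   $\sum P(i,j)(i-\mu_i)(j-\mu_j)/(\sigma_i\sigma_j)$. The four per-angle
   5-vectors are averaged element-wise into one 5-vector $g$.
2. **LBP block (256 values).** Each interior pixel is compared with its 8
   neighbors ($P=8$, $R=1$, i.e. the 3×3 square); neighbor $\ge$ center
   contributes its power-of-two bit. The 256-bin code histogram $l$ is
   normalized to sum 1.
3. **Interaction block (1280 values).** The outer product
   $M = g \otimes l$, $M_{ij} = g_i l_j$, flattened row-major: every entry
   couples one second-order statistic with one local-pattern frequency.
4. **Aggregated block (3 values).** Sum, mean and median of $g$.
5. **Statistical block (3 values).** Population variance, skewness and
   excess kurtosis of $g$ (all with $1/m$ normalization, $m = 5$).

Concatenated in that order the descriptor has
$5 + 256 + 5\cdot256 + 3 + 3 = 1547$ dimensions. An optional sixth block
applies $x \mapsto \log(1+x)$ to $g$; because the 1547 total is only
consistent with that block being absent, the reference configuration
excludes it, and a flag either appends it (length 1552) or substitutes it
for the raw GLCM block (length 1547 again). Both readings of the source
material are exposed; the package does not resolve which was deployed.
The interaction block always uses the raw $g$.

## Conventions that the literature leaves open

Several choices are not forced by the formulas; each is fixed once and
documented here:

* **Energy.** "Energy" sometimes means the angular second moment
  $\sum P^2$ and sometimes its square root. The default is
  $\sqrt{\sum P^2}$ (the common library convention, and the one that keeps
  energy in $(0,1]$); `glcm_config(energy = "asm")` selects the other.
* **Correlation at zero variance.** A constant image has
  $\sigma_i\sigma_j = 0$; correlation is then defined as 1 (perfect
  self-correlation), matching prevalent library behavior and keeping
  constant textures finite.
* **LBP tie rule and bit order.** The comparison is `neighbor >= center`
  (ties set the bit), applied literally — a constant image maps to code
  255 everywhere. Bits are enumerated clockwise from the top-left
  neighbor. Any fixed order only permutes histogram bins consistently, so
  within-run comparability is unaffected; the order is part of the
  package's contract.
* **Degenerate moments.** For a constant $g$ (std 0) skewness and
  kurtosis are defined as 0.
* **Grayscale conversion.** RGB collapses via BT.601 luma
  (0.299, 0.587, 0.114), then round-half-up quantization to
  `[0, levels-1]`; grayscale input is only quantized. No resizing is
  performed: every block is size-normalized, so the pipeline is
  resolution-agnostic. No denoising is applied — the descriptor operates
  on the image as read.
* **GLCM levels.** Default 256 (no quantization loss on 8-bit input);
  configurable down to 8, which speeds the matrix up at some loss of
  intensity resolution.

## Classifier and metric battery

A linear-kernel soft-margin SVM (cost $C = 1$ by default) is trained
one-vs-rest: one binary libsvm fit per class (via e1071), with the
explicit weight vector and bias extracted so prediction is a deterministic
matrix product and per-class decision values are available for ROC
analysis. Features are z-scored with training-set statistics only — raw
GLCM contrast and LBP frequencies differ by about five orders of
magnitude, and a linear SVM on the unstandardized blocks is
ill-conditioned. The hinge-loss formulation of libsvm is used; on the
separable problems this package targets, the distinction from
squared-hinge variants is immaterial.

Evaluation derives per-class one-vs-rest counts from the confusion matrix
and reports accuracy, precision, recall, F1, sensitivity, specificity,
TPR, FPR, FNR, TNR and Dice per class plus macro averages, alongside
pooled (micro) accuracy. Per-class Dice is computed as
$2TP/(2TP + FP + FN)$ and is algebraically identical to per-class F1; the
code computes them from one expression so the identity is bit-exact. A
class absent from both truth and prediction gets Dice 1 by the
empty-vs-empty convention, with a warning flag. Rates with zero
denominators are reported as 0. (Dice is reported because the original
comparison tables quote a "DSC" for this classification model, although
DSC is normally a segmentation-overlap measure; here it can only mean the
confusion-matrix Dice.)

ROC curves sweep thresholds over each class's decision values; tied
scores collapse to one operating point, which under trapezoidal
integration equals the pairwise convention "ties count half". The
micro-average pools all (score, binary label) pairs across classes. Note
that pooled micro-AUC compares decision values *across* classes, so it is
sensitive to score calibration in a way per-class AUC is not.

The learning curve stratified-subsamples the table at each requested
fraction and runs k-fold cross-validation (default 5), reporting training
and validation accuracy mean and SD per size.

## The synthetic data generator

Real MRI cannot ship with the package, so end-to-end behavior is
demonstrated on synthetic textures designed to be distinguishable by
exactly the statistics the descriptor measures, without claiming visual
realism:

* `smooth_field` — Gaussian white noise blurred with a Gaussian kernel
  (default correlation length 8 px): spatially correlated, low local
  contrast, high homogeneity (the role of a smooth, diffuse texture);
* `fine_noise` — i.i.d. uniform noise: maximal local contrast;
* `oriented_grating` — a sinusoid (default period 8 px, orientation 0°,
  i.e. horizontal stripes) plus 10% uniform noise: strongly anisotropic,
  which the four-angle GLCM resolves.

Defaults span the full 8-bit range on 64×64 images. Each image is a pure
function of (class spec, dataset seed, image index): the per-image seed is
a fixed polynomial hash of the three, so any image can be regenerated
without generating the whole set, and datasets are bit-identical across
runs and platforms (integer pixels). Generation saves and restores the
global RNG state.

What passing the end-to-end tests shows — and does not. The default
three-class problem (100 images per class, 64×64, 80/20 stratified split)
is linearly separable in the composite space, and the suite requires
held-out macro accuracy and macro-F1 of at least 0.95 with training
accuracy 1.0 at every learning-curve size, mirroring the behavior reported
for the real 3064-slice archive. This validates the pipeline's mechanics
and the descriptor's sensitivity to second-order structure; it says
nothing about intensity inhomogeneity, partial-volume effects, skull and
background anatomy, patient-level variability, or class imbalance in real
MRI. The Figshare reproduction is deliberately left to the optional
`.mat` reader plus the command-line tools, outside the test suite.

Problem sizes used by the automated checks (all chosen as comfortable
desk-scale experiments): oracle comparisons on 16×16 8-level images;
end-to-end runs on 48×48 or 64×64 images with 8–100 images per class;
metric fuzzing over 500 random confusion matrices; AUC cross-checks on up
to 50 scores.

## Numerical notes and limitations

* GLCM accumulation is exact integer counting (`tabulate` over level
  pairs) before normalization; properties are vectorized sums, checked
  against a term-by-term double-loop oracle at $10^{-10}$.
* Feature CSVs are written at 17 significant digits, so write-then-read
  reproduces doubles exactly; metrics JSON and feature CSV are
  byte-identical across reruns of the same configuration and seed.
* libsvm's decision-value sign follows its internal order-of-appearance
  label convention; the wrapper normalizes it so each class's score is
  positive on that class's side.
* Only the 8-neighbor, radius-1 LBP is implemented (no rotation-invariant
  or uniform variants), GLCM distances are limited to the configured
  integer `S` with the four axis-aligned angles, and no feature selection
  is performed. Timing of the original study is not reproduced
  (hardware-dependent).
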