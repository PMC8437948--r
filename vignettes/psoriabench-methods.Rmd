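---
title: "Methods: synthetic lesion scenes, segmentation, features and severity scoring"
author: "psoriabench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic lesion scenes, segmentation, features and severity scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

psoriabench is a workbench for image-based assessment of psoriasis
severity from local (close-up) lesion photographs. It covers the full
chain: a seeded generator of psoriasis-like scenes with ground truth,
automatic lesion segmentation, five-indicator segmentation evaluation,
decomposition of a lesion into erythema and scale patch images, crop and
affine augmentation, texture/colour/spectrum feature extraction,
three-filter consensus feature selection, six severity classifiers under
repeated stratified cross-validation, and PASI aggregation. This
vignette explains the models and the design choices; every number quoted
is recomputed by the test suite or by `scripts/acceptance.R`.

## The severity model

Clinical grading of a local psoriasis photograph scores two visible
indicators, erythema (redness) and scaling (white keratin flakes), each
on an integer 0-4 scale. The severity group of an image is banded on
the score sum: healthy (0), mild (1-2), moderate (3-4), severe (5-6),
very severe (7-8); `severity_group()` implements exactly this banding.
The full PASI score additionally grades thickness and affected area over
four body regions,

$$\mathrm{PASI} = 0.1\,(E+T+S)_h A_h + 0.2\,(E+T+S)_u A_u +
  0.3\,(E+T+S)_t A_t + 0.4\,(E+T+S)_l A_l,$$

with $E,T,S \in \{0..4\}$, area grade $A \in \{0..6\}$, and $h,u,t,l$
the head, upper extremities, trunk and lower extremities; the range is
0-72 (`pasi_score()`). Thickness and area need 3-D information that a
single local photograph does not carry, so the imaging pipeline models
erythema and scaling only and `pasi_score()` is a standalone aggregator.

## The synthetic scene generator

Clinical photographs of this kind are not publicly deposited, so the
package ships a generator (`generate_scene()`) whose output exercises
every pipeline stage with known ground truth. A scene is rendered in
CIE-L\*a\*b\* and converted to sRGB at the end:

* **Skin background** — constant base tone (default L\*a\*b\* ≈
  (70, 12, 18)) plus a low-amplitude smoothed noise texture, a
  multiplicative shading ramp in a random direction (amplitude 6 L\*
  units by default, emulating body curvature), and dark quadratic-Bezier
  strokes for hairs (15 by default).
* **Lesions** — 1-4 blobs, each the super-level set
  $1 + 0.35\,z(x) - s(x) > 0$ of a smoothed Gaussian random field $z$
  against normalised radial distance $s$; this produces the irregular,
  ambiguous boundaries that make real lesions hard to segment, unlike
  elliptical phantoms.
* **Erythema** — inside each blob, a\* is raised by
  `erythema_score * erythema_a_gain` (default gain 8 Lab units per score
  unit) with a falloff at the boundary whose width *grows as the score
  decreases* (0.12-0.52 in normalised radius), so mild lesions have the
  blurriest margins. The erythema ground-truth mask is the falloff core
  (weight ≥ 0.5).
* **Scaling** — a high-frequency smoothed-noise field thresholded at the
  quantile that makes the speckle cover `scale_score *
  scale_coverage_gain` (default 0.12/unit) of the lesion area, rendered
  near-white (high L\*, low chroma). The threshold-by-quantile
  construction makes measured coverage track the request; a property
  test holds it within ±20% relative over 20 seeds.
* **Invariants** — a healthy scene (both scores 0) has no lesions and
  empty masks; erythema and scale masks are disjoint subsets of the
  lesion mask; everything is bit-reproducible from the seed.

What the generator does *not* emulate: camera noise and compression,
specular highlights, perspective and body-part geometry, multiple skin
tones in one population (the base tone is a single parameter), and
co-occurring non-psoriatic conditions. Passing tests therefore show the
pipeline is correct and well-behaved on controlled input; they do not
certify clinical accuracy.

The bundled experiments (tests and the acceptance script) render scenes
at 256 × 256 with the generator's clinical dials at their defaults; the
default rendering size for interactive use is 512 × 512.

## Segmentation

`segment_slic()` is the automatic method: SLIC superpixels in the 5-D
space (L\*, a\*, b\*, x, y) with combined distance
$d = d_{lab} + (m/S)\,d_{xy}$ (compactness $m = 10$, $S$ the grid
interval; 700 superpixels, 10 assignment sweeps, connectivity enforced
by absorbing orphan components), followed by k-means of the
per-superpixel mean colours into 3 centres (500 iteration cap). The
secondary k-means uses k-means++ seeding with 8 restarts, keeping the
lowest within-cluster sum of squares: with a single start it can settle
on splitting skin by illumination while a small lesion cluster merges
into skin — the restarts make isolating a tight red cluster the winning
solution.

Which cluster is "lesion" is not specified by the 3-centre model, so the
package defines selection rules: `max_a` (default; erythema is by
definition the reddest cluster), `a_above_median`, and `manual`. A
contrast guard (`min_a_contrast`, default 5 Lab units over the image
median a\*) empties the mask when no cluster is convincingly red, which
is what makes healthy images segment to (near-)nothing. Cleanup closes
the mask with a disc of radius 3 (recovering scale speckle at the
boundary), fills holes (interior scale), and drops components below 25
px.

`segment_lsm()` is the semi-automatic alternative: a two-phase
reaction-diffusion level set initialised from a user-supplied seed mask
as a signed binary step. Each of the 15 iterations takes one explicit
evolution step (step size $\Delta t_1 = 1$) of an edge-stopped signed
pressure force toward the inside/outside intensity midpoint, scaled by
$|\nabla\varphi|$, then a diffusion sub-step
$\varphi \mathrel{+}= \Delta t_2 \Delta\varphi$ ($\Delta t_2 = 0.001$).
The field is clamped to $[-1, 1]$ each iteration for stability; the
mask is $\{\varphi > 0\}$. On a constant image the force vanishes and
the mask stays at the initialisation; with $\Delta t_2 = 0$ the
diffusion sub-step is the identity.

Segmentation quality is scored by `evaluate_segmentation()`: Dice,
global consistency error, variation of information (bits), Hausdorff
distance (pixels) and Rand index, all on the two-region partition a
binary mask induces. Conventions for identical and empty masks: an
identical pair scores (1, 0, 0, 0, 1); two empty masks are identical
segmentations (Dice 1, VoI 0, GCE 0, RI 1) but the Hausdorff distance to
an empty set is undefined and errors (reported as `NA` by the composite).
VoI is reported with its standard orientation — 0 means identical, lower
is more similar. Every metric is verified against an independent
brute-force implementation on random small masks to 1e-9.

## Patch decomposition

`decompose_lesion()` converts the lesion pixels to L\*a\*b\* and
k-means-clusters them (k = 3 by default: erythema, scale, transitional
tissue; k-means++ with 4 restarts, 300 iteration cap). Clusters are
labelled by their colour statistics — erythema is the cluster with
maximum mean a\*, scale the one with maximum mean L\* among the rest —
because redness and whiteness are the defining colour signatures of the
two symptoms. Patch images keep the original RGB values on the
component mask and zero everything else, so downstream masked feature
extraction is unambiguous. Patch images are never augmented; the
dataset assembler records them untransformed.

## Augmentation and dataset assembly

Two datasets mirror the two augmentation regimes: **A** = crops only,
**B** = crops plus 11 affine variants per kept crop (rotations 90°,
180°, 270°; horizontal flips of identity and the three rotations;
uniform ×1.25 and ×0.8 scalings; ×1.25 stretches along x and y). A crop
grid of 3×2 is used when the aspect ratio is ≥ 1.4, else 2×2; tiles
partition the image exactly. Crops whose lesion fraction is below 1%
are discarded — except crops of healthy images, whose empty mask is
their expected state. The ×12 row multiplier of dataset B (original +
11 variants) holds exactly when nothing is filtered. The aspect
threshold, grid layouts and the four scaling factors are package
defaults chosen for reproducibility and are all configurable.

## Features

All features are computed over the lesion or patch mask only; healthy
crops (empty mask) are described by whole-crop statistics. The pools
are fixed, ordered and name-stable:

* **texture (33)** — GLCM statistics (contrast, correlation, energy,
  homogeneity, entropy; 32 grey levels, distance 1, averaged over 4
  directions), GLRLM statistics (SRE, LRE, GLN, RLN, RP, LGRE, HGRE over
  4 directions), intensity histogram moments (mean, variance, skewness,
  kurtosis, energy, entropy over 64 bins), semi-variogram
  $\gamma(h)$ at lags 1, 2, 4, 8 plus its slope over $\log h$, and the
  uniform LBP histogram (P = 8, R = 1, 10 bins).
* **colour (27)** — mean and standard deviation of all 12 channels of
  RGB, HSV, CIE-L\*a\*b\* (sRGB companding, D65 white) and full-range
  BT.601 YCbCr, plus skewness of a\* and L\* and the erythema index
  (mean a\* − mean b\*).
* **spectrum (49)** — Gabor magnitude mean/sd per orientation ×
  frequency (0°, 45°, 90°, 135° × 0.1, 0.2, 0.4 cycles/px; zero-mean
  kernels, σ = 0.56/f) and Zernike moment magnitudes to radial order 8
  on the mask's bounding circle, normalised by the masked mean
  intensity.

Quantisation to 32 levels and the Haralick protocol (distance 1, four
angles, angle-averaged) are the common defaults; grey-level texture uses
BT.601 luma. Zernike magnitudes and angle-averaged GLCM statistics are
rotation-stable to better than 1% under 90° rotations. A note on exact
invariances: on a square pixel grid a centred constant disk cancels
Zernike moments exactly only for angular orders not divisible by 4; the
remaining orders keep a small discretisation residue, which is why the
tests split the tolerance.

## Feature selection

Three filters rank the active feature set independently: greedy mRMR
with the mutual-information-difference criterion (equal-width 10-bin
discretisation), the chi-squared statistic of the binned-feature ×
class table, and ReliefF (all samples as anchors, k = 10 nearest
hits/misses, range-normalised Manhattan distances, miss contributions
weighted by class priors). Each method keeps its top ⌈2p/3⌉ features
and the final set is the three-way intersection; an empty intersection
is an error rather than a silent fallback. The greedy mRMR sequence is
oracle-checked against exhaustive criterion evaluation for p ≤ 8, and
the consensus recovers 5 planted informative features out of 50 in ≥
90% of seeds.

## Classification and evaluation

Six classifier families (`classifier_spec()`): ECOC-SVM (one-vs-one
coding over binary RBF SVMs, minimum-loss decoding), Gaussian naive
Bayes, k-NN (k = 5, Euclidean on standardised features), random forest
(100 bagged trees), multiclass AdaBoost (SAMME over depth-1 trees, 100
rounds), and a four-layer fully connected network (hidden sizes
256-128-64, ReLU, softmax cross-entropy, Adam at learning rate 0.001,
batch 32, 200 epochs, no early stopping). Where the underlying
binary/ensemble learners are standard they come from e1071,
randomForest, class and rpart; the ECOC decoding, boosting loop and
network are part of the package.

`cross_validate()` runs stratified k-fold CV (default 5 folds) repeated
10 times. Features are z-scored from the training fold only; an
optional selection hook runs inside each training fold by default (no
selection leakage), or once on the whole data when explicitly requested
for comparison. Each fold yields a confusion matrix and seven metrics:
accuracy, sensitivity, specificity, precision, F1 (macro-averaged
one-vs-rest for 3+ classes; classic positive-class definitions for 2×2),
the generalised multiclass Matthews correlation coefficient and Cohen's
kappa. F1 is the headline metric of `run_experiment()`, which evaluates
a grid of dataset variants × the seven feature combinations ×
classifiers and records failed cells as `NaN`.

## Numerical and degenerate-input choices

* k-means: k-means++ seeding, Lloyd iterations, empty clusters re-seeded
  from the farthest point; restarts pick minimum WCSS; ties in
  assignments break to the lowest index, making everything deterministic
  under a seed.
* Rank ties in feature selection break by original feature order.
* Metrics guard division by zero: per-class rates with empty
  denominators are excluded from macro averages; MCC and kappa are 0
  when their denominators vanish (chance-level agreement).
* Masks are stored as 0/255 PNG (foreground = 255); grey PNGs binarise
  at 50% intensity. YCbCr values are clamped to [0, 255].
* The Hausdorff distance refuses empty masks ("distance to nothing" is
  undefined) instead of returning a sentinel.

## Problem sizes of the bundled experiments

The test suite and acceptance script use: 200 random mask pairs (≤ 8×8)
for metric oracles; 20 seeded severe scenes (erythema 4, scaling 2,
256²) for segmentation and patch recovery; a balanced 10-scene dataset
(2 per group, 256²) expanded to dataset B (~400 crops/variants) with
texture + colour features for the end-to-end classification check
(5-fold CV × 10 repeats, random forest and k-NN); 20 seeds × (150 × 50)
matrices for selection recovery. A full run of the suite takes a couple
of minutes on one core.

## Known limitations

Synthetic scenes are easier than clinical photographs: a single skin
tone, no specularities, no camera pipeline, and a colour contrast that
directly encodes the severity scores. Crops from the same scene can
land in different CV folds, so the end-to-end F1 measures within-scene
generalisation, not patient-level generalisation. The 3-centre colour
clustering assumes at most three colour populations inside the
observation window; multiple dissimilar lesions in one image can share a
cluster. The level-set front moves at most about one pixel per
iteration, so with the default 15 iterations the seed mask must lie
within ~10-15 px of the target boundary.
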