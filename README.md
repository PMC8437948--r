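# psoriabench

Image-based assessment of psoriasis severity from local lesion
photographs, as a tested, end-to-end R workbench. It is aimed at
researchers building or evaluating computer-aided severity scoring:
people who need a reproducible reference chain from a photograph to a
severity grade, with ground truth at every stage.

Clinical grading of a close-up psoriasis photograph scores two visible
indicators, **erythema** (redness) and **scaling** (white keratin
flakes), each 0-4; the severity group is banded on the score sum
(healthy, mild 1-2, moderate 3-4, severe 5-6, very severe 7-8). The
full **PASI** score aggregates erythema, thickness and scaling with an
area grade over four body regions:

```
PASI = 0.1 (E+T+S)_h A_h + 0.2 (E+T+S)_u A_u + 0.3 (E+T+S)_t A_t + 0.4 (E+T+S)_l A_l
```

with E, T, S in 0-4, A in 0-6 and range 0-72.

The package implements:

* a seeded **synthetic lesion-scene generator** (skin tone, shading,
  hairs; irregular lesion blobs whose redness follows the erythema score
  and whose white speckle coverage follows the scaling score), with
  ground-truth lesion/erythema/scale masks — so every stage is testable
  without clinical images;
* **segmentation**: SLIC superpixels in (L\*, a\*, b\*, x, y) (700
  superpixels) + 3-centre colour k-means with a reddest-cluster
  selection rule, and a reaction-diffusion **level set** alternative
  (Δt₁ = 1, Δt₂ = 0.001, 15 iterations) seeded from a mask;
* **five similarity indicators** (Dice, GCE, VoI, Hausdorff, Rand),
  each verified against a brute-force oracle;
* **patch decomposition** of a segmented lesion into erythema and scale
  patch images by k-means in CIE-L\*a\*b\*;
* **augmentation** (4/6-way crops; rotations, flips, scalings; lesion
  content filter) building datasets A (crops) and B (crops + 11 affine
  variants each);
* **feature extraction** over the mask: texture (GLCM, GLRLM, histogram,
  semi-variogram, uniform LBP = 33), colour (RGB/HSV/Lab/YCbCr
  statistics + erythema index = 27), spectrum (Gabor bank + Zernike
  magnitudes = 49);
* **three-filter consensus selection** (mRMR, chi-squared, ReliefF; top
  2/3 each, intersected);
* **six severity classifiers** (ECOC-SVM, naive Bayes, k-NN, random
  forest, AdaBoost, a 4-layer Adam-trained network) under repeated
  stratified cross-validation with seven metrics (accuracy, sensitivity,
  specificity, precision, F1, MCC, kappa);
* **PASI aggregation** and a one-call `run_pipeline()` orchestrator plus
  a thin CLI (`exec/psoriabench`).

## Worked example

```r
library(psoriabench)

scene <- generate_scene(lesion_scene_params(image_size = 256,
                                            erythema_score = 4,
                                            scale_score = 2, seed = 7))
scene
#> <lesion_scene> 256 x 256, E=4 S=2 (severe), lesion fraction 0.092

seg <- segment_slic(scene$image)
evaluate_segmentation(seg$mask, scene$lesion_mask)
#> Segmentation similarity (higher is better: DICE, RI; lower: GCE, VoI, HD)
#>   DICE 0.9421 | GCE 0.0182 | VoI 0.1326 bits | HD 6.00 px | RI 0.9800

patches <- decompose_lesion(scene$image, seg$mask, seed = 1)
lab <- rgb_to_lab(scene$image)
mean(lab[, , 2][patches$erythema_mask])   # erythema patch: strongly red
#> [1] 40.1
mean(lab[, , 1][patches$scale_mask])      # scale patch: near-white
#> [1] 83.3

severity_group(4, 2)$group
#> [1] severe
pasi_score(data.frame(region = "trunk", E = 2, T = 1, S = 1, A = 3))
#> [1] 3.6
```

The Dice of 0.94 says the automatic mask overlaps 94% of the ground
truth (1 = perfect); GCE/VoI near 0 and RI near 1 agree; the Hausdorff
distance bounds the worst boundary error at 6 px. The patch statistics
confirm the two symptom components were separated by colour: the
erythema patch is strongly red (a\* ≈ 40 vs ≈ 12 for skin) and the scale
patch near-white (L\* ≈ 83 vs 70).

For the classification stage, assemble a dataset and cross-validate:

```r
scenes <- generate_dataset(2, "scenes", seed = 1, image_size = 256)
ds <- assemble_dataset(scenes, dataset_spec("B"), "scenes", "dataset")
fm <- extract_matrix(ds, "dataset", groups = c("texture", "color"))
xy <- feature_xy(fm)
rep <- cross_validate(classifier_spec("rf", seed = 1), xy$X, xy$y,
                      cv_config(k_folds = 5, repeats = 10, seed = 1))
glance(rep)   # seven aggregate metrics, one row
autoplot(rep) # per-fold metric distributions
```

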