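# cystct

Classification of pancreatic cystic lesions on axial CT slices: serous
cystic neoplasms (SCN, benign, typically microcystic/"honeycomb") versus
mucinous cystic neoplasms (MCN, malignant potential, typically uni- or
oligo-locular). Distinguishing the two matters clinically because MCNs are
resected while most SCNs are watched, yet their CT appearance overlaps.

The package implements a full image-to-decision pipeline for radiologists'
outlined ROIs, plus a synthetic phantom cohort so every stage runs and is
testable offline:

1. **Segmentation.** From a manual lesion outline, either the
   outline-masked single-channel image, or the *semi-automatic rectangle*:
   the tight bounding box of the outline expanded 2 pixels outward, so the
   patch contains the whole lesion plus a thin band of surrounding tissue.
2. **Multi-channel conversion.** The HU patch becomes a 3-channel image:
   display-windowed grayscale (default WL 40 / WW 400 soft-tissue window,
   mapped linearly to [0, 1]), the Canny edge map of that plane, and its
   max-normalised Sobel gradient magnitude.
3. **Feature extraction.** Classic texture families — GLCM/Haralick, LBP,
   HOG, Gabor bank, Haar-wavelet subband statistics — or a seeded
   fixed-weight convolutional extractor with a global-pooling output
   (64-d `tiny_cnn`, 2048-d `resnet_pool`).
4. **Classification.** KNN (vote-fraction probabilities), softmax
   (L2-regularised logistic regression), Gaussian naive Bayes and SVM
   (Platt-calibrated), fused either by three-voter majority voting or by
   **MMRF stacking**: a random forest trained on the bases'
   *out-of-fold* positive-class probabilities

   p_i = P_base_i(MCN | x),  meta: P(MCN | x) = RF(p_1, p_2, p_3),

   which weights more accurate bases higher without target leakage.
5. **Evaluation.** The six standard indicators — precision TP/(TP+FP),
   sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy,
   F1 = 2·precision·sensitivity/(precision+sensitivity), and rank-based
   (Mann–Whitney) AUC — under image-level or patient-level 80/20 splits.

Patient CT cohorts of this kind are not publicly deposited, so the
`phantoms` module generates seeded CT-like slices (hypodense fluid,
brighter septa partitioning the lesion into locules, parenchyma background,
Gaussian noise) in which SCN-like lesions have many small locules and
MCN-like lesions one or few — the texture contrast the classifiers must
exploit.

## Worked example

Four experiment arms on the same 200-slice phantom cohort (20 synthetic
patients × 5 slices per class), GLCM features, patient-level 80/20 split:

```r
library(cystct)

man <- run_experiment(experiment_config(preprocessing = "manual_roi",  seed = 11))
mc  <- run_experiment(experiment_config(preprocessing = "multichannel", seed = 11))
vot <- run_experiment(experiment_config(classifier = "voting", seed = 11))
fus <- run_experiment(experiment_config(classifier = "mmrf",   seed = 11))
compare_table(list(manual = man, multichannel = mc, voting = vot, mmrf = fus))
#>              Precision Sensitivity Specificity Accuracy F1 score  AUC
#> manual          62.50%      75.00%      55.00%   65.00%   68.18% 0.82
#> multichannel   100.00%      75.00%     100.00%   87.50%   85.71% 0.99
#> voting         100.00%      80.00%     100.00%   90.00%   88.89% 0.97
#> mmrf           100.00%      75.00%     100.00%   87.50%   85.71% 0.97
```

Rows are pipeline arms, columns the six indicators on the held-out
patients (8 patients, 40 slices). The multichannel rectangle clearly beats
the outline-masked single-channel arm — the rectangle preserves the
lesion/parenchyma boundary and internal septa that the edge and gradient
channels then amplify — and probability fusion performs on par with the
best single classifier on this small test side.

The fitted stacking model is an ordinary S3 model object:

```r
fus$model
#> Stacked random-forest fusion model (MMRF)
#>   bases: knn, softmax, bayes | meta: random forest (200 trees)
#>   n = 160, 5-fold out-of-fold stacking, positive class MCN
```

with `predict()` (fused probability or hard label), `summary()`
(per-base out-of-fold AUC and meta-forest importance) and `plot()`
methods.

A thin CLI wrapping the same functions lives at `inst/cli/cystct.R`
(`phantoms`, `experiment`, `compare` verbs).

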