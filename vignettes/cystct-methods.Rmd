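---
title: "Methods: multi-channel CT preprocessing, texture features and stacked classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-channel CT preprocessing, texture features and stacked classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystct)
```

## The problem

Serous (SCN) and mucinous (MCN) pancreatic cystic neoplasms look similar
on CT but are managed very differently: MCNs carry malignant potential and
are resected, most SCNs are observed. Radiologically the discriminating
signal is largely *internal architecture*: SCNs tend to be microcystic
("honeycomb", many small locules separated by thin septa), MCNs uni- or
oligo-locular. cystct turns a radiologist's lesion outline on an axial
slice into that decision via texture/CNN features and classifier fusion.

## Pipeline and its assumptions

**Segmentation.** Two paths from the outline. The *manual* path keeps only
outlined pixels, blanking the rest to the bottom of the display window
(−160 HU under the default window); feature extractors then see the lesion
against a uniform dark field, and the lesion/parenchyma interface is an
artificial outline-shaped edge. The *rectangular* path takes the tight
bounding box of the outline and expands it 2 pixels outward (clipped at
the image border), preserving real surrounding tissue and the true lesion
boundary. Coordinates are 0-based and inclusive on both ends, which makes
the 2-pixel expansion literal integer arithmetic; boxes are never padded
to squares here — resampling is owned by the feature extractors.

**Multi-channel conversion.** The HU patch is mapped through a display
window (level 40 HU, width 400 HU by default — the standard soft-tissue
abdomen window; the linear map sends [WL−WW/2, WL+WW/2] to [0, 1] with
clamping). Channel 2 is the Canny edge map of the *windowed* plane,
channel 3 its Sobel gradient magnitude rescaled by its own maximum.
Computing channels 2–3 after windowing is a deliberate choice: the window
then controls which HU contrasts can produce edges, exactly as it controls
what a reader sees. Canny defaults are sigma 1 px with hysteresis
thresholds at 0.1/0.2 of the maximum gradient; all of these are exposed
(`window_spec()`, `canny_params()`). Max-normalisation of the gradient is
the minimal monotone "enhancement" transform; anything stronger (gamma,
equalisation) would add a parameter the data cannot currently calibrate.

**Features.** The handcrafted families consume the windowed channel only
(the edge and gradient channels are binary/derived and would dominate
histogram statistics): GLCM over 32 uniform gray levels with offsets
{(0,1),(1,0),(1,1),(1,−1)} summarised by contrast, correlation, energy,
homogeneity and entropy; LBP with 8 bilinearly interpolated neighbours at
radius 1 into a 256-bin normalised histogram; HOG on a 64×64 bilinear
resize with 8×8 cells, 2×2 blocks, 9 unsigned orientation bins; a Gabor
bank of 4 frequencies × 4 orientations reporting response-magnitude mean
and SD; and a 2-level orthonormal Haar decomposition reporting per-subband
energy and entropy. Every descriptor has constant length for a fixed
configuration, so feature matrices are rectangular. The convolutional
extractor consumes all three channels, resized and standardised per
channel, through a fixed seeded He-initialised network to global average
pooling (64-d small stack, or a residual stack with a 2048-d pooled
output). The network is never trained: classification happens downstream
on extracted features, which keeps the whole artifact reproducible offline
with no weight downloads. The softmax "classifier head" is therefore an
ordinary multinomial logistic fit on features, uniform across extractors.

**Classification.** Base learners are deliberately standard: KNN with
k = 5 (odd, so binary votes cannot tie; probability = vote fraction),
softmax as ridge-penalised logistic regression (glmnet, fixed lambda),
Gaussian naive Bayes, and an RBF SVM with Platt-calibrated probabilities.
The fusion model `mmrf()` stacks the three default bases: 5 stratified
folds produce out-of-fold P(MCN) per base; a 200-tree random forest is fit
on that n×3 matrix; bases are refit on all training data for deployment.
Out-of-fold construction is the standard leakage-free way to train a
meta-learner — the forest sees each base's honest generalisation
behaviour, so better bases get more influence. Meta-features are the
positive-class probabilities only; the complement column is redundant in a
binary problem. The positive class is MCN everywhere (the clinically
actionable call), and a fused probability of exactly 0.5 is assigned to
MCN.

**Evaluation.** Six indicators (precision, sensitivity, specificity,
accuracy, F1, AUC), with AUC computed by the rank (Mann–Whitney) estimator
with half-credit ties — identical to the trapezoidal area under the
empirical ROC, which the tests verify against an exhaustive pair-counting
oracle and pROC. Zero-denominator metrics return 0 with a warning rather
than erroring, so degenerate predictors cannot abort a batch comparison.
Statistical comparison of two models' AUCs on the same cases is a paired
permutation test (score-swap within cases); no parametric AUC-variance
method is claimed. Splitting defaults to *patient level* — all slices of
one synthetic patient on one side — because same-patient slices are
strongly correlated; an image-level stratified mode is provided for
protocols defined at the image level, with the caveat that it leaks
intra-patient correlation into the test side.

## The phantom cohort

No patient CT cohort of this kind is publicly deposited, so the package
generates one. Each slice is 128×128 with a single elliptical lesion
(semi-axes 15–30 px, random orientation): fluid 10 HU, septa 60 HU,
parenchyma 90 HU, additive Gaussian noise SD 10 HU. These values are
declared, not fitted — plausible unenhanced soft-tissue contrast with
hypodense cyst fluid — since no intensity statistics exist to calibrate
against. Internal architecture encodes the radiological distinction:
SCN-like lesions draw 6–12 locule seed points, MCN-like 1–3; septa are the
~2 px wide ridges of the seeds' Voronoi partition plus a 2 px rim, the
simplest construction that yields honeycomb-vs-unilocular edge structure.
A synthetic patient contributes several slices sharing one lesion geometry
and differing only in noise realisation, creating exactly the
intra-patient correlation that makes patient-level vs image-level
splitting a meaningful contrast. Datasets serialise as 16-bit grayscale
TIFF (stored value = HU + 1024, exact round-trip), 0/255 PNG masks and a
CSV manifest with relative paths, so a dataset directory is byte-stable
under relocation.

What the phantoms do *not* emulate: organ anatomy and neighbouring
structures, contrast phases, partial-volume and beam-hardening effects,
scanner noise texture, reader variability in outlines, and class overlap —
phantom classes are considerably cleaner than patient data. Passing the
pipeline-discrimination tests therefore shows the machinery extracts and
uses internal-architecture texture correctly; it does not certify clinical
performance.

## Problem sizes, determinism and numerical choices

Routine experiments in the tests use 6–20 patients × 2–5 slices per class;
the headline surrogate runs 200 images (20×5 per class) with an 80/20
patient split — small enough to run in seconds yet large enough for stable
AUCs. One global experiment seed fans out to per-stage seeds by hashing
stage names (`derive_seed()`), so the phantom draw, the split, every base
fit and the meta-forest are individually reproducible; re-running an
experiment with one seed rewrites byte-identical prediction files.
Degenerate inputs are handled explicitly: constant planes produce empty
edge maps and zero gradients (with a tolerance guard against
floating-point residue), zero-variance channels standardise to zero, a
constant GLCM patch reports correlation 1, and empty masks, single-class
labels, undersized patches and mismatched dimensions raise classed errors.

## Known limitations

Automatic lesion segmentation is out of scope — a human outline is input.
Only two classes are supported. The convolutional extractor's random
weights are a reproducible stand-in for a pretrained backbone, adequate
for texture this coarse but not a claim about transfer-learned features.
DICOM input is not read; images enter as HU-offset TIFF/PNG. Phantom
realism is declared rather than calibrated, so absolute metric values on
phantoms should not be compared against patient-cohort numbers.
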