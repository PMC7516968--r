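---
title: "Methods: segmentation, feature fusion, and imbalance-aware evaluation in lesionfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, feature fusion, and imbalance-aware evaluation in lesionfuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

lesionfuse implements a computer-aided detection (CAD) pipeline for
classifying pigmented skin lesions in dermoscopy images as melanoma or
nevus. This vignette is the package's account of the underlying methods:
the model at each stage, the tunable parameters and their defaults, the
numerical choices made where the design was genuinely open, what the
synthetic-data generator does and does not emulate, and the known
limitations.

## Pipeline overview

`cad_fit()` chains the stages in a fixed, leakage-free order:

1. **Segmentation** — blur, CIELab conversion, per-channel mean
   thresholding, mask intersection, majority filtering, lesion component
   resolution, bounding-box crop (`preprocess()`).
2. **Handcrafted features** — a 43-element descriptor of asymmetry,
   shape, color, and texture (`handcraft_vector()`).
3. **Deep features** — a frozen feature extractor applied to the resized
   ROI (`extract_deep()`); concatenated after the handcrafted block
   (`concat_features()`).
4. **Stratified 75/25 split** (`split_data()`), then z-score
   normalization fitted on the training partition only
   (`zscore_fit_apply()`).
5. **Fusion by mutual information** — per-feature MI with the label,
   mean-MI threshold selection (`mi_scores()`, `select_features()`),
   estimated on the training partition only.
6. **SMOTE balancing** of the training partition (`smote()`).
7. **Shallow classification** (`train_classifier()`) and evaluation on
   the untouched test partition (`metrics_report()`).

Every statistic that could leak information about the test partition
(normalization moments, MI scores, SMOTE interpolants) is computed on the
training partition alone. Where the literature on this pipeline family
leaves the relative order of normalization, selection, and balancing
open, we fix the leakage-free order above and record it in the run
report.

## Segmentation

Skin and lesion are separated in CIELab because the three channels
decorrelate lightness (L, 0–100) from chroma (a*, b*), and pigmented
lesions are darker and less chromatic than surrounding skin on all three
axes. Each channel of the blurred image is thresholded at its own mean;
the three binary maps are intersected, so a skin pixel must exceed the
mean on L *and* a* *and* b*. A 5×5 majority (median) filter removes
speckle.

Numerical choices:

* **Gaussian blur, `sigma = 3` px.** The blur exists to suppress hair and
  speckle before thresholding. At the native 450×600 scale, σ = 3
  flattens strokes a few pixels wide while moving the apparent lesion
  edge by only ~3 px (the mean-threshold crossing of a blurred step edge
  sits about `sigma * qnorm(1 - margin/contrast)` outside the true
  boundary — ~3.3 px for the typical 7-L-unit margin against a 50-L-unit
  contrast). Box-recovery tests therefore use a ±5 px tolerance.
* **Thresholding runs on the blurred image**; the ROI crops are taken
  from the original, so downstream features see unsmoothed data.
* **Majority filter border handling.** The vote runs over the in-bounds
  part of each window. Zero padding would erode a lesion touching the
  crop edge and turn an all-foreground mask into a ring; the in-bounds
  vote is the variant that leaves solid masks invariant.
* **Lesion polarity and component choice** (`lesion_mask()`). The
  intersection marks bright skin as 1, but polarity can flip for unusual
  palettes, and either polarity may contain several components. The
  lesion is the largest 8-connected component — over foreground *and*
  background components — that does not touch the image border: lesions
  are interior, skin reaches the frame. Each polarity is first cleaned by
  a morphological opening with a 5-px disc, and the selected component by
  a second opening whose diameter scales with the component size
  (`2*floor(sqrt(area)/30)+1`, at least 5 px). The rationale is a width
  separation: residual hair fragments are tens of times thinner than any
  lesion, so an opening at a few percent of the lesion diameter removes
  attached hair stubs without reshaping the blob. If every candidate
  touches the border the largest component overall is used, with a
  warning.
* **Coordinates** are 0-based, half-open, row-major throughout.
* a*/b* are reported on the standard sRGB/D65 scale (roughly ±128); the
  narrower ±30 range sometimes quoted for dermoscopy material is treated
  as descriptive of typical values, not as a different transform.

## The 43-element handcrafted descriptor

Order: `symmetry`, `area`, `perimeter`, `circularity`, `diameter`,
`eccentricity`, 24 color statistics, 13 texture statistics.

**Asymmetry.** For each principal axis of the mask (eigenvectors of the
second-central-moment matrix, through the centroid), the mask is
reflected about the axis and scored `1 − FS/A`, where `FS` is the area of
the symmetric difference between mask and reflection and `A` the area of
their union; the two axis scores are averaged. This reproduces both
boundary cases exactly: a self-coincident shape scores 1, a reflection
disjoint from the original scores 0. The reflection is rasterized by
*inverse* mapping — a pixel belongs to the reflection iff its mirror
image lands on a lesion pixel — because forward-mapping pixel centers
through an oblique reflection and rounding leaves ~20% aliasing holes,
which would depress the score of perfectly symmetric shapes to ~0.8.

**Shape.** Area is the pixel count. The perimeter is the length of the
0.5-level contour of the mask, smoothed by a short circular moving
average (window ±2 vertices) before measuring: the raw marching-squares
polygon overestimates smooth boundaries by ~6% (staircase effect), while
the smoothed length of digital discs is within a few tenths of a percent
of the true circumference, keeping the circularity `4π·area/perimeter²`
of a disc at ≈ 1. Diameter and eccentricity come from the image-moment
ellipse: with eigenvalues λ₁ ≥ λ₂ of the second-central-moment matrix,
diameter = 4√λ₁ (the major-axis length of the ellipse with matching
moments) and eccentricity = √(1 − λ₂/λ₁). One-pixel-wide masks clamp
eccentricity to 1 with a warning.

**Color.** Min, max, population variance, and mean of each of R, G, B,
L, a*, b*, computed over lesion pixels by default (`lesion_only = TRUE`);
the whole rectangular crop is available as an option. Population (not
sample) variance matches the moment convention used by the texture
statistics.

**Texture.** Haralick statistics of the gray-level co-occurrence matrix
(GLCM). Defaults: luminance gray (0.299R + 0.587G + 0.114B) quantized to
`Ng = 32` equal-width levels over [0, 255]; distance 1; angles 0°, 45°,
90°, 135°; symmetric accumulation; the 13 statistics computed per offset
and averaged. Only pixel pairs with both ends inside the lesion mask
contribute (in the default lesion-only mode). Natural logarithms are used
for all entropy-family features, with 0·log 0 ≡ 0. The 13 features are
ASM, contrast, correlation, variance, IDM, entropy, sum average, sum
variance, sum entropy, difference variance, difference entropy, and the
two informational measures of correlation. The descriptor set is
sometimes printed with only 12 texture equations but a stated count of
13; sum average is the standard member completing the set, and
1 + 5 + 24 + 13 = 43 is the only decomposition consistent with the stated
total. Correlation divides by the standard deviations σₓσᵧ (printed
moment definitions are variances; dividing by variances would not yield a
correlation in [−1, 1]). The second informational measure is implemented
as `1 − exp(−2(HXY2 − HXY))` as printed (without the customary square
root); both variants lie in [0, 1] and differ by a monotone transform.
Degenerate single-cell GLCMs define correlation and IMC1 as 0.

**TDS utility.** `tds_score()` implements the clinical Total
Dermatoscopic Score `1.3A + 0.1B + 0.5C + 0.5D` with cutoffs 4.75
(benign/suspicious) and 5.45 (suspicious/malignant), for clinically
scored inputs; it is not derived from the image features.

## Deep features

Pretrained CNN backbones are treated as frozen generic feature
extractors: resize the ROI (bilinear), apply the network, rectify, and
globally pool to a fixed-length nonnegative vector. The package ships the
*contract* — `feature_extractor()`, a registry of the standard output
dimensions (VGG16/19: 4096, ResNET-50, Inception v3, Xception: 2048,
Mobilenet v1: 1024, Mobilenet v2: 1280, DenseNET-201: 1920) — and a
deterministic surrogate (`surrogate_extractor()`): `dim` random 3×3×3
convolution filters drawn once from a seed, ReLU, global average pooling,
on a 64×64 resize. The surrogate is content-sensitive and bit-repeatable,
which is exactly what the pipeline and its tests require; real backbones
plug in through the `backend` argument of `deep_extractor()` without any
change elsewhere. Which layer a real backbone should expose is taken to
be the penultimate (post-global-pool) layer matching the registry
dimensions.

## Mutual-information fusion

Each feature's MI with the binary label is estimated and the arithmetic
mean of all scores is the selection threshold: only features scoring
*strictly above* the mean survive (if all scores are equal, the single
highest-scoring feature is kept so the selection is never empty).

The default estimator is the Ross k-nearest-neighbor estimator for mixed
continuous–discrete data: for each point, the Chebyshev distance to its
k-th nearest neighbor *within its own label class* defines a radius; `m`
counts all points (any label, self included) strictly inside that radius;
the estimate averages `ψ(N) − ψ(N_y) + ψ(k) − ψ(m)` over points and
clamps negatives to 0. Choices:

* `k = 3`, the standard small-k default of this estimator family.
* Duplicate values are broken by a deterministic jitter at 1e-10 of the
  column's spread, seeded per column — the standard remedy for the
  zero-distance degeneracies discrete ties would cause.
* The inner loop is in C++ (sorted one-dimensional arrays, two-pointer
  neighbor search, binary-search radius counts), so scoring a
  2000 × 1000 table takes about a second.
* `cad_fit()` caps k at what the training partition supports
  (`min(k, min class count − 1, (n−2)/2)`) and falls back to the binned
  estimator for degenerate partitions.

A plug-in binned estimator (`mi_binned()`, equal-width bins, default 16)
is provided as the low-variance alternative. The two agree within 0.05
nats on smooth one-dimensional problems at n = 5000.

A property worth knowing when interpreting selections: with ~1000
features of which ~10 are informative, the *mean*-MI threshold sits just
above the kNN estimator's finite-sample noise floor (sd ≈ 0.007 nats at
n = 2000), so besides all informative features, a tail of noise features
(~20%) also survives; the binned estimator's much tighter noise floor
keeps that tail below 1%. This is intrinsic to the estimator (the
reference implementation of the same estimator behaves identically), not
an artifact of this implementation. Selection is repeatable: ties and
jitter are deterministic.

## Balancing and normalization

SMOTE equalizes the training class counts: each synthetic minority point
is `x_i + u·(x_nn − x_i)` with `u ~ U(0, 1)` and `x_nn` one of the
`k = 5` nearest minority neighbors (Euclidean distance); base points are
cycled so generation is spread evenly; synthetic rows are flagged in a
provenance column. SMOTE runs *after* MI selection and only on the
training partition — balancing before the split (or selecting on the full
table) would let synthetic points interpolate test information into
training. z-score normalization uses training-partition means and
(sample) standard deviations; constant columns pass through unscaled with
a warning.

## Classifiers and evaluation

Logistic regression (`glm`), SVM with linear or RBF kernel (e1071;
`C = 1`, `γ = 1/p` by default, inputs pre-scaled so `scale = FALSE`), and
an optional relevance vector machine via kernlab, run in regression mode
on ±1 labels with a 0 threshold — the standard adaptation, since the
installed RVM backend is regression-only. SVM decision values are
oriented at training time so larger scores always mean more
melanoma-like. The default classifier is `svm_rbf`.

Melanoma is the positive class everywhere. Besides accuracy, sensitivity,
specificity, precision, F-score (`2tp/(2tp+fp+fn)`), and Matthews
correlation, the imbalance-aware family is reported: G-mean
`√(sens·spec)`, dominance `sens − spec`, and the index of balanced
accuracy `IBA = (1 − dominance)·G-mean²`. AUC is the rank (Mann–Whitney)
statistic of the continuous scores, ties counting ½. Because published
operating-point tables in this area sometimes print an "AUC" close to
(sens + spec)/2, the report includes `balanced_accuracy` separately so
the two cannot be conflated. Published G-mean/IBA columns are not always
consistent with the defining formulas applied to the printed
sensitivity/specificity (e.g. a printed 0.90/0.80 where the formulas give
0.88/0.81); the formulas are authoritative here and the discrepancy is
left documented rather than resolved. Undefined ratios (zero
denominators) are reported as NaN with a warning rather than silently
as 0.

## The synthetic-data generator

`make_lesion_image()` emulates the features the pipeline consumes, with
exact ground truth: a skin-colored background (default RGB 224/172/150,
Lab ≈ 74.6/16.1/18.7); a centred, rotated ellipse whose interior is tiled
with blobby patches of 1–6 palette colors; controllable bilateral
asymmetry; hair-like quadratic arcs; additive Gaussian pixel noise
(default sd 2). Defaults follow the imaging conditions of the public
dermoscopy archives this pipeline family targets: 450 × 600 RGB frames
with one centred lesion occupying ~13% of the frame.

Design notes:

* **Palette order.** The six clinical lesion shades are ordered so the
  leading (default) colors — dark brown, black-brown, gray-brown,
  blue-gray — sit below typical skin on all of L, a*, b*, the regime the
  three-channel mean-threshold intersection targets. Red and light brown
  have chroma above skin; with substantial area they shift a channel mean
  past the skin value and defeat this segmentation method — a real
  limitation of mean thresholding, reproducible by choosing those colors.
* **Asymmetry** is a one-sided sinusoidal radial bump (up to +50% of the
  local radius on one half of the boundary at level 1), so ground-truth
  asymmetry is controllable and measured symmetry decreases monotonically
  in the level.
* **Hairs** are thin dark (1 px, 60% blend) or wider faint (2–3 px, 20%
  blend) strokes: prominent to the eye yet within the contrast/width
  regime that blur + majority filtering can suppress. Wide fully opaque
  occlusions defeat mean thresholding and are outside the artifact class
  the generator emulates — the package deliberately contains no hair
  inpainting.
* Generators restore the session RNG state; all randomness derives from
  the seed stored in the generator specification object.

What the generator does **not** emulate: photorealistic skin texture,
vignetting, gel bubbles, rulers and ink marks, multi-lesion frames, and
the full class structure of real archives. Passing tests on generator
images therefore demonstrates the pipeline's mechanics — segmentation
accuracy against ground truth, descriptor stability, selection and
balancing behavior, reproducibility — not clinical performance on real
dermoscopy data, which additionally requires pretrained backbones and a
real image archive.

`make_feature_table()` generates labelled tables with a known information
structure (informative columns are standard normal with a
class-conditional mean shift; fixed-count minority sampling), the unit of
the fusion/balancing test suites.

## Problem sizes used by the tests

The test and acceptance suites run the full pipeline at reduced canvas
sizes (typically 160×200 to 300×400 for images, 40-image corpora,
2000 × 1000 feature tables), chosen so the whole suite completes in well
under a minute of compute per stage while the segmentation margins scale
like the native resolution. The generator's own defaults stay at the
native 450 × 600 scale; the acceptance script uses them unchanged.

## Known limitations

* Mean thresholding assumes one interior lesion darker than skin on all
  three Lab channels; high-chroma (red/white) or frame-touching lesions
  break the assumption (the polarity/component rule then falls back with
  a warning).
* The blur moves the detected boundary outward by ~σ, so masks are
  slightly dilated; shape features are computed on the detected mask,
  not the ground truth.
* Marginal (per-feature) MI ignores redundancy and interactions;
  duplicated informative features are both kept, and the mean-MI
  threshold adapts poorly to heavy-tailed score distributions (see the
  fusion section).
* The kNN MI estimator requires each class to have more than k members;
  tiny corpora fall back to the binned estimator inside `cad_fit()`.
* SMOTE interpolates in the selected feature space; it cannot invent
  genuinely new minority structure and can blur class boundaries when
  the minority class is multi-modal.
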