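---
title: "Trainable segmentation and morphometrics of enamel rods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trainable segmentation and morphometrics of enamel rods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tooth enamel is built from quasi-cylindrical rods of hydroxyapatite about
5 µm in diameter, sheathed by roughly 0.5 µm of interrod enamel. In many
mammals the rods decussate: alternating bands in which rods run mostly in
the section plane (parazones) or mostly out of it (diazones), the
arrangement that produces Hunter-Schreger bands and toughens enamel
against crack propagation. Etched sections imaged by SEM show each rod as
a bright cross-section over darker interrod enamel; the out-of-plane tilt
(*pitch*) of a rod is recoverable from the shape of that cross-section.

Quantifying decussation therefore requires three steps: segment rods from
etch texture, fit each rod's cross-section, and turn the fits into angles
and band statistics. `rodseg` implements that pipeline:

1. **Feature expansion.** Each pixel's single intensity is expanded into a
   high-dimensional descriptor by the convolutional layers of the VGG16
   architecture, used frozen. Pooling and activation layers are omitted so
   every layer keeps full image resolution and each pixel receives the
   concatenated responses of the selected layers -- between 64 features
   (shallowest layer alone) and 4224 (all 13 convolutional layers).
2. **Pixel classification.** A random forest maps feature vectors to
   {rod, background}. Only the forest is trained; no network training
   occurs.
3. **Morphometrics.** The predicted mask is despeckled, components are
   fit with moment ellipses, and each rod receives pitch
   $\theta = \sin^{-1}(b/a)$, yaw, solidity, and a
   parazone/diazone/rejected classification.
4. **Validation.** Predicted rod tables are registered against ground
   truth by centroid proximity (±5 px) and paired pitch values are scored
   against the identity line.

Because annotated SEM data cannot ship with a package, a synthetic
generator renders decussated-enamel images with pixel-exact ground truth;
all tests and the acceptance script run on it.

## The canonical frame and pixel scale

The reference acquisition is 640 × 520 px at 500× nominal magnification,
imaging a field of view of about 244 µm across. We calibrate a single
isotropic pixel size from the width: 244/640 = 0.38125 µm/px, and treat
the scale as inversely proportional to magnification. The stated field of
view actually implies slightly anisotropic pixels (the height would give
0.277 µm/px); since the ellipse-angle arithmetic requires one isotropic
scale, we calibrate from the width only and expose the constant in
`canonical_frame`. All physical thresholds live in µm and are converted
per image, so this choice is visible and revisable in one place.

Images at other magnifications (400-600× supported) are first padded with
black pixels (mag > 500) or centre-cropped (mag < 500) to
`round(size × mag/500)` and then resampled bilinearly to 640 × 520, after
which rods have the same pixel dimensions as at native 500×. Cropping is
centre-anchored and padding symmetric (extra pixel to the bottom/right);
masks, when resampled, use nearest-neighbour to stay binary.

## What the synthetic generator emulates

`synthetic_spec()` describes an idealised decussated surface. Design
choices that matter:

* **Rod geometry.** Each rod is the cross-section of a tilted cylinder:
  the drawn minor axis $b$ equals the rod diameter (default 5 µm) and the
  major axis follows $a = b/\sin\theta$, so the drawn ellipse encodes the
  true pitch exactly through $\theta = \sin^{-1}(b/a)$. Parazone pitch is
  drawn from 18-25°, diazone from 35-65°. The parazone lower bound keeps
  a *single* in-plane rod's cross-section ($a \le 16.2$ µm, area
  $\le 63.6$ µm²) below the 70 µm² bound used downstream to reject
  *merged* rods; genuinely lower pitches produce band-truncated stripes
  that the elliptical-rod idealisation cannot represent without
  conflating single rods with merged ones.
* **Bands.** Vertical parazone/diazone stripes with a 60 µm period
  (half each), a plausible Hunter-Schreger spacing of several rod widths.
  Rods sit on a per-band jittered lattice with spacing set by the rod
  envelope plus the 0.5 µm interrod gap, so rods never overlap; a
  rasterisation guard drops boundary pixels that would 8-connect two
  rods, keeping truth rows in exact 1:1 correspondence with mask
  components. With `merge_probability > 0` lattice neighbours are
  deliberately bridged to exercise the merged-rod filters.
* **Density.** A fill fraction of 0.62 leaves roughly 300-600 rods per
  canonical frame -- the density of a manually annotated micrograph --
  covering about a third of the canvas.
* **Intensity model.** Rods at 0.62 ± per-rod jitter (s.d. 0.05) over a
  0.35 background, a ±0.05 left-right shading ramp, and additive Gaussian
  etch-texture noise (s.d. 0.12). These defaults were chosen from a
  signal-to-noise argument: single-pixel intensity thresholding then
  misclassifies ~13% of pixels, so a classifier must use spatial context
  to do well, but cannot reach 100% -- the regime a trainable segmenter
  is for. Real etch texture is structured rather than white, real
  backgrounds contain crystallite detail, and real masks carry annotator
  subjectivity; passing on synthetic data therefore demonstrates the
  machinery is correct, not that any particular accuracy will transfer
  to microscope data.

## Feature expansion choices

The architecture's 13 convolutional layers carry
64, 64, 128, 128, 256 ×3, 512 ×6 filters (their sum is the 4224-feature
upper bound; the three dense layers cannot produce per-pixel maps and are
excluded). Convolutions are 3 × 3, zero-padded "same", evaluated
sequentially with pooling and activations removed, so the map is linear
in the image for zero-bias kernels -- a property the tests exploit
against a direct convolution oracle.

Two weight backends share one contract. The `vgg16` backend consumes
pretrained kernels and biases supplied locally as an RDS file (weights
are not bundled). The `filterbank` backend substitutes seeded Gaussian
kernels of identical shapes, scaled by $1/\sqrt{9\,C_\text{in}}$ to keep
variance stable through the linear chain, with zero biases. It is
deterministic, dependency-free, and clearly *not* equivalent to
pretrained weights -- it exists so the pipeline is runnable and testable
offline. Per-image intensity standardisation before expansion is
available behind `normalize_intensity` and defaults to off.

## Classifier choices

"Standard random-forest parameters" is pinned to: unlimited depth,
$\sqrt{p}$ candidate features per split, Gini impurity, bootstrap
sampling, 150 trees by default (50 for the brute-force layer search).
The forest is a probability forest, so each pixel gets a vote-fraction
rod probability; masks threshold at 0.5 with ties going to rod. Class
imbalance is left unweighted by default, with `class_weights` available.

Training pools per-pixel rows over all (flip-augmented) training images.
Only left-right and top-bottom flips are applied -- harsher distortions
break pixel-level image/mask correspondence. A seeded per-image pixel
subsample (`subsample_fraction`) bounds training cost;
`subsample_fraction = 1` reproduces exact pooling. The default is 0.02
(~60,000 rows for three augmented canonical frames), chosen so a full
end-to-end run finishes in minutes on one core: learning curves for this
per-pixel task flatten far below that row count, and the held-out
accuracy at 0.02 is indistinguishable from larger samples in our runs.

The brute-force layer search trains one 50-tree forest per candidate
selection on the *unaugmented* training images and scores pixel accuracy
on the held-out image; results are ranked descending with ties broken by
fewer features, then lexicographic layer ids. Internally the
convolutional chain is evaluated once per image over the union of
candidate layers and sliced per selection. Five-fold cross-validation
groups pixels by source image when at least five images are present,
falling back to pixel-level folds with a warning.

## Morphometric conventions

* **Ellipse fit.** Normalised second central moments with full axis
  lengths $a = 4\sqrt{\lambda_1}$, $b = 4\sqrt{\lambda_2}$ -- the
  convention of mainstream region-property tools, under which a disk of
  diameter $d$ yields $a = b = d$.
* **Connectivity.** 8-neighbour components; 4-connectivity would split
  diagonally touching etched rods.
* **Despeckle.** Components strictly below 20 px are removed first; the
  operation is idempotent.
* **Angles.** Yaw is the major-axis angle from the image vertical,
  positive clockwise as displayed, folded to (-90°, 90°] with -90°
  reported as +90° (an axial quantity). Pitch is $\sin^{-1}(b/a)$ in
  degrees; $b > a$ beyond 10⁻⁹ relative tolerance is treated as an
  upstream bug, not data. Average parazone yaw uses the axial circular
  mean (double-angle method) because arithmetic means misbehave near
  ±90°.
* **Filters and precedence.** Minor axis $b \ge 5.5$ µm →
  `rejected_merged_minor_axis`; else area > 70 µm² →
  `rejected_merged_area`; else pitch > 25° → `diazone`, otherwise
  `parazone`. The precedence (speckle → minor axis → area → pitch) only
  affects the rejection label, never which rods are retained. Area
  filtering is strict at exactly 70 µm², mirroring a stipulated maximum;
  pitch is strict at 25° ("greater than"). Border-touching rods are
  retained and flagged.
* **Cross-band profiles.** The analysis axis is either supplied
  explicitly (e.g. an operator-traced dentin-enamel junction direction)
  or set perpendicular to the average parazone yaw; retained rods
  contribute (projected centroid position in µm, pitch).

## Validation conventions

The ±5 px registration tolerance is read as a per-coordinate box, with
greedy nearest-Euclidean one-to-one matching among in-box candidates.
The primary R² is computed about the identity line,
$1 - \sum(\hat\theta-\theta)^2 / \sum(\theta-\bar\theta)^2$, because the
criterion is agreement with the line of equality, not the goodness of an
arbitrary linear fit; the free-fit R² is reported alongside. Degenerate
cases (fewer than two pairs, zero truth variance) return `NA` with a
warning rather than 0, so pipeline faults are not masked. An identity
R² above 0.90 flags the segmentation as significantly similar to truth.

## Problem sizes used by the tests

The test-suite and acceptance script run at sizes chosen as a desk-scale
study design: the end-to-end property run uses the full canonical
640 × 520 suite (3 training + 1 held-out specimens, flip augmentation,
150 trees, 2% pixel subsampling); the layer-search study uses quarter-
area 320 × 260 specimens and a six-selection pool over the first four
layers, reflecting the screening spirit of a 50-tree brute-force search.
Deeper layer pools are supported but the pretrained-equivalent depth
(filter counts up to 512) is exercised at small grid sizes, where the
feature-count and linearity contracts are exact.

## Known limitations

* 2-D sections cannot recover the sign of diazone pitch; the pipeline
  reports magnitudes only.
* Merged rods are filtered out rather than split (no watershed step).
* The filter-bank backend is a stand-in for texture learning, not a
  pretrained-feature replica; absolute accuracies with it are not
  comparable to runs with pretrained weights.
* The synthetic generator draws ideal ellipses; it does not model
  crystallite substructure, anisotropic etch texture, or annotator
  noise, so quantitative results on it bound only rasterisation and
  pipeline error.
* Scale-bar detection and mosaicking of >600× tiles are out of scope;
  magnification must be supplied by the operator.
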