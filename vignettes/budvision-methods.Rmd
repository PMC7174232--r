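---
title: "Methods: synthetic plates, contour morphometrics and the two classification branches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic plates, contour morphometrics and the two classification branches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budvision)
```

## The problem

Dried chrysanthemum tea is graded by eye: seven commercial products
(Hangbaiju, Huangshangongju, Kunlunxueju, Hangtaiju, Kunlunmiju, Huaiju and
Dabieshantaiju) differ in harvest stage — three are picked in full bloom,
four at the tighter, pre-bloom "fetal" stage — and in size, outline and
colour. budvision implements two automated grading pipelines over plate
images of loose buds:

* a **morphological branch**: backlit grayscale plates are denoised,
  thresholded and segmented, each bud's outline is traced, fourteen contour
  descriptors are computed, and grid-searched KNN/MLP/SVM classifiers
  predict flowering stage (2 classes) and product type (7 classes);
* a **raw-image branch**: hand-held colour photographs on fiducial-marked
  paper are rectified, each bud is cropped, resampled to 50 x 50 RGB, and a
  compact convolutional network is trained end to end.

No public image set exists for this task, so the package also contains a
synthetic plate generator with analytic ground truth; it is first-class,
tested code, and every empirical claim made by the test suite is computed on
it at run time.

## The synthetic generator and what it does (not) emulate

Bud silhouettes are star polygons `r(theta) = R (1 + a cos k theta)` with up
to three additional low-order random harmonics, optional elongation and
rotation. The model captures what drives the fourteen descriptors — size,
anisotropy, and petal frill (which directly controls the radial-variance
"irregularity" features) — while remaining star-shaped, so rasterization is
an exact pixel-centre inclusion test and canonical shapes (circle, ellipse,
square) have closed-form descriptor values for oracle testing.

Per-class sampling ranges mirror the published relative sizes: Huangshangongju
is drawn largest and Kunlunmiju/Huaiju smallest, and Kunlunxueju and
Hangtaiju overlap in size even though they differ in stage, which is what
makes the 7-class shape task genuinely hard. Bloom classes carry a stronger
frill (amplitude 0.08-0.20 versus 0.02-0.08 for fetal classes), standing in
for open petals; this calibration makes the 2-class stage task nearly
separable, matching the observation that stage is easy and type is hard for
shape features.

Gel mode renders dark silhouettes at a fixed transmittance level on a bright
16-bit field with Gaussian and salt-and-pepper noise. Phone mode renders
coloured, multiplicatively textured silhouettes on white paper with four
QR-like concentric-square fiducials centred on the corners of the square
sample area, then applies a linear illumination gradient, a soft elliptical
shadow, a random projective warp and sensor noise. Instances sit on a
non-overlapping grid (16 per frame by default, within the 16-25 per shot of
the acquisition protocol) with a small centre jitter; shapes larger than 45%
of the cell pitch are rejected at render time, which also guarantees an
unambiguous row-major reading order.

Deliberately **not** emulated: touching or overlapping buds (the reference
plates show separated buds; watershed splitting is out of scope), lens
distortion, JPEG compression artifacts, colour constancy effects, and any
photorealistic petal texture. Consequently a green test suite here shows the
pipeline machinery is correct and the study's qualitative findings are
reproducible under the stated generative assumptions — not that the exact
published accuracies transfer to real plates (the original images were never
deposited, so those numbers are unreproducible by anyone).

## Plate processing

* 3 x 3 median filter with edge replication (gel branch only).
* Otsu thresholding on a 256-bin histogram after min-max rescaling; the
  **dark** class is foreground in both modes (transmittance silhouettes;
  buds darker than paper). The exhaustive between-class-variance scan is the
  test oracle. Because binning happens after min-max rescaling, the gel
  pipeline is invariant to global linear intensity rescaling.
* 8-connected components with a 64 px^2 speck filter (configurable). The
  reading order groups components into rows by vertical-interval overlap,
  then sorts left to right — a plain lexicographic sort on bounding-box
  corners would interleave rows when large and small buds share one row.
* Outer contours by Moore-neighbour border following with Jacob's stopping
  criterion, counter-clockwise, holes ignored; filling the traced chain (a
  4-connected background flood) reproduces the mask exactly on simply
  connected shapes, and the suite asserts this identity.
* Fiducial detection is structural: dark components are paired into
  (border ring, core) candidates by concentricity and the 7:3 bounding-box
  ratio, and each pattern is localized by a darkness-weighted centroid.
  Rectification maps the four centres to the corners of an `out_px` square
  with bilinear resampling; on rectified plates, components touching the
  image border (the quarter fiducials) are dropped before cropping.

Coordinates are 0-based with x = column and pixel centres at integer
positions; masks live on tight bounding boxes with a `(x0, y0)` offset.

## The fourteen descriptors

Perimeter (chain length including the closing edge), area (pixel count),
long axis (exact maximum pairwise contour distance, computed on the convex
hull, which attains the maximum), short axis (extent of the filled mask
along the line through the centre of mass perpendicular to the long axis;
pixels within half a pixel of the line count as on it), incircle radius
(maximum of the exact Euclidean distance transform), excircle radius
(Welzl's minimum enclosing circle), area-equivalent diameter, circularity
`4 pi A / P^2`, shape parameter `P^2 / A`, aspect ratio, compactness,
roundness `incircle/excircle`, and the radial-variance pair: irregularity is
the population variance of contour-point distances to the centre of mass,
and normalized irregularity the population variance after dividing by the
mean distance.

Choices worth stating explicitly:

* The area-equivalent diameter is `sqrt(4A/pi)` — the equivalent-disk
  diameter; the bare ratio `4A/pi` has units of area and cannot be a
  diameter.
* "Centre of mass" is the filled-region centroid, not the centroid of
  contour points, which is biased by boundary sampling density.
* Population (not sample) variance: the contour is the entire population of
  boundary points.
* Contour distances are taken at raw 8-connected boundary pixels without
  arc-length resampling, so irregularity carries a mild resolution
  dependence; the scale-equivariance tests budget 5% for it, and under
  off-grid rotations the pair can move by up to ~10% at benchmark scales
  (boundary pixel density is direction-dependent on a raster), so exact
  rotation invariance is asserted only at 90-degree multiples.
* When several contour pairs tie for the maximum distance (exactly possible,
  since squared distances of integer points are integers), the short axis is
  measured for every tied direction and the largest extent is kept; this
  makes the descriptor well-defined and exactly invariant under 90-degree
  rotations.

## Shape classification protocol

Stratified 9:1 train/test split; all model selection happens by 10-fold
stratified cross-validation on the training set only. Features are z-scored
with train-only population statistics, and the scaling is refit inside each
CV fold — refitting per fold is the leakage-free variant of standardizing
once before splitting, and on this data changes results negligibly.

Grids: KNN `k = 1..5` crossed with Minkowski power `p = 2, 3`; MLP single
hidden layer of `5, 7, ..., 29` units with ReLU or tanh and the Adam solver;
RBF-SVM `C = 2^0..2^10` crossed with `gamma = 2^-8..2^0`. Ties in mean fold
accuracy resolve to the earliest candidate in canonical enumeration order
(k then p; hidden size then ReLU before tanh; C then gamma). The SVM is
e1071/libsvm; KNN and the MLP are implemented in the package because no
installed backend offers Minkowski `p = 3` neighbours or a ReLU/Adam
single-layer perceptron. The MLP runs full-batch Adam (learning rate 1e-3,
at most 1000 iterations) and stops early when the loss fails to improve its
running best by 1e-4 for 10 consecutive iterations or is essentially zero —
the usual plateau criterion for this family of solvers. KNN votes break ties
by the nearest neighbour among the tied classes.

PCA is the eigenstructure of the covariance of the standardized features;
each loading's largest-magnitude element is made positive so score plots are
sign-stable.

## The convolutional branch

Crops are resampled straight to 50 x 50 (aspect ratio not preserved — the
protocol specifies only the target size) by separable Keys bicubic
interpolation (`a = -0.5`), giving the 7,500-neuron input. The network is a
stack of 2-5 stages, each **conv -> ReLU -> batch norm -> average pool** in
that order (batch norm after ReLU as specified, although conv-BN-ReLU is the
more common arrangement), then a fully connected softmax head; a linear map
to the class count is structurally required even though only the softmax is
named. Convolutions are "same"-padded with stride 1. Average pooling uses
window = stride with **ceiling-mode sizing and edge replication**: the
canonical pool sequence 2, 8, 4, 2 on a 50-px input is only feasible under a
ceiling convention (50 -> 25 -> 4 -> 1 -> 1; floor mode collapses to zero),
so that convention is adopted and a pooling window may exceed its input,
acting as global pooling. Training is RMSProp (decay 0.9, epsilon 1e-8) at a
constant learning rate of 1e-4, minibatch 128, categorical cross-entropy, at
most 100 epochs, seeded weight initialization (He) and epoch shuffling.
After training, batch-norm inference statistics are recomputed exactly over
the training set ("precise" batch norm): with only a handful of minibatches
per epoch the exponentially averaged running statistics lag the final
weights, and the recomputation makes evaluation on the training set agree
with the final training accuracy, as the evaluation contract requires.

Architecture comparison trains the nine canonical candidates and selects by
accuracy on a 10% validation split carved from the training data, ties going
to the smaller parameter count; comparing candidates on the test set — which
is what the historical protocol appears to do — is available behind
`paper_mode = TRUE` but leaks the test set into selection and is not the
default.

The layers are implemented in vectorised base R (convolution as k^2 shifted
BLAS products in an (H, W, N, C) layout, pooling as separable 1-D linear
operators, so backward passes are exact transposes) with two small compiled
kernels for the per-channel batch-norm affine maps.

## Problem sizes and numerical choices

The test suite and the acceptance script run the benchmark at 30 instances
per class (210 total, the spec's acceptance scale), 640 px gel plates and
phone sample areas, and train the CNN for 15-30 epochs with minibatches
shrunk to keep several gradient steps per epoch at small n — colour-separable
crops saturate within a few epochs, and the spec-level defaults (100 epochs,
batch 128) remain the package defaults. Oracle suites use 500 random masks
up to 64 x 64 and exhaustive 256-bin threshold scans on 100 random images.
Rasterization treats a pixel as inside if its centre satisfies the continuous
inequality (with a 1e-9 slack so exact boundaries include their pixels);
homographies are fit by the 8-unknown DLT and inverted analytically, and
warping resamples bilinearly. All randomness flows through per-call seeds
saved and restored around each generator, so every artifact is a pure
function of (configuration, seed).

## Known limitations

* Touching buds are never generated and would be merged by segmentation.
* The irregularity pair is resolution-dependent by construction (no
  arc-length resampling of the contour).
* The synthetic colour model (flat colour + smooth multiplicative texture)
  is far simpler than real petal texture; CNN accuracies on it are upper
  bounds on realism, which is why acceptance checks are phrased as contrasts
  (CNN versus shape features on colour-only classes) rather than absolute
  accuracy targets.
* Shadows and illumination gradients are mild enough for a single global
  Otsu threshold; heavier, bimodality-breaking lighting would require local
  thresholding that the reference protocol does not include.
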