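---
title: "Chorio-retinal boundary segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chorio-retinal boundary segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(octseg)
```

## The problem

Enhanced-depth-imaging OCT B-scans of the posterior eye show, from top to
bottom, the vitreous, the retina, the choroid and the sclera. Three
boundaries delimit these regions: the inner limiting membrane (ILM), the
outer boundary of the retinal pigment epithelium (RPE), and the
choroid-scleral interface (CSI). Choroidal thickness — the RPE-to-CSI
distance — is the clinically interesting quantity, and the CSI is by far the
hardest boundary to locate because the choroid sits behind the
hyper-reflective RPE and its posterior edge is weakly contrasted.

`octseg` implements two supervised segmentation pipelines that share a
common final stage:

1. **Patch-based classification.** Small patches (32x32 to 128x32 pixels,
   height x width) are classified into four classes — centred on the ILM,
   RPE or CSI boundary, or background (BG). Classifying a patch centred on
   every pixel yields one probability map per boundary.
2. **Semantic segmentation.** A U-Net variant labels every pixel of the
   full B-scan with its region (vitreous / retina / choroid / sclera);
   per-boundary probability maps are the positive part of the vertical
   Sobel response of the relevant region-probability plane.

In both cases each probability map becomes a directed graph — one vertex
per pixel, edges to the right / upper-right / lower-right neighbour with
weight

$$ w_{sd} = 2 - (P_s + P_d) + w_{\min}, \qquad w_{\min} = 10^{-5}, $$

where $P_s$ and $P_d$ are the source and destination vertex probabilities —
and the boundary is the minimum-cost path found by Dijkstra's algorithm. A
column of probability-1 vertices, connected top to bottom, is appended to
each side of the map so that no manual start or end point is needed: the
path can enter and leave the image at any row at near-zero cost.

## The synthetic phantom

The clinical dataset that motivates the package layout (1536 x 496 px
B-scans, 3.9 um/px vertical and 5.7 um/px horizontal, participant-split
train/validation/evaluation sets) is not distributable, so the package
ships a phantom generator that every stage is trained and tested against.
`phantom_params()` defaults describe the study-format geometry:

* three boundaries as sums of 2–4 random-phase sinusoids around mean depths
  of (120, 200, 290) rows — a ~300 um retina and ~350 um choroid at
  3.9 um/px — with curvature amplitude 15 px and the shortest wavelength
  bounded below by `curvature_smoothness` (200 columns). Ordering is
  enforced by clamping each lower boundary at least 2 px below the one
  above, which makes the `ilm < rpe < csi` invariant testable by
  construction;
* four region intensities (15, 130, 90, 150 gray levels): dark vitreous,
  bright retina, darker vascular choroid, brighter sclera;
* multiplicative gamma speckle with mean 1 and standard deviation 0.3, the
  standard first-order OCT speckle approximation;
* exponential depth attenuation `exp(-0.002 * row)`, losing roughly two
  thirds of the signal over the 496-row scan depth, which is what the
  attenuation-compensation step is designed to undo;
* `shadow_count` vertical vessel-shadow bands that multiply intensities
  below the ILM by `shadow_attenuation`;
* annotations dropped with probability 1/2 within `missing_margin` columns
  of either edge, mirroring edge shadows in real exports.

`phantom_params_scaled(width, height)` rescales this geometry to smaller
rasters, keeping relative anatomy and total depth attenuation fixed.

What the phantom does **not** emulate: real choroidal vascular texture,
drusen or pathology, the optic nerve head, instrument vignetting, or motion
artefacts. Passing the end-to-end tests therefore demonstrates that the
pipeline machinery is correct and can learn layered-tissue structure under
speckle, attenuation and shadows — not that the shipped defaults reach
clinical accuracy on patient data.

## Networks and training

No deep-learning framework is assumed: the package carries a compact CPU
training engine (`R/nn-core.R` plus C++ convolution/pooling kernels) with
hand-written backpropagation, verified against central-difference numeric
gradients in the test suite. Layers: zero-padded convolutions, batch
normalisation before every ReLU, 2x2 max pooling, nearest-neighbour
up-sampling, dropout, fully-connected stages, bidirectional recurrent
sweeps (vertical and horizontal tanh RNNs), and channel / spatial
squeeze-and-excitation blocks.

**Patch models** (`build_patch_model()`): a Cifar-style CNN (three 5x5
conv/pool stages, two FC stages), a deeper/wider "complex" CNN (five 3x3
conv stages), and a ReNet-style RNN sweeping 2x2 tiles vertically then
horizontally with 32 filters per direction. The RNN has the fewest
parameters, the complex CNN by far the most (asserted in tests). No dropout
in the CNNs; a light dropout between the RNN sweeps. The exact kernel
tables of the original classifiers are not fixed by the sources this
package follows, so the stage structure (simple CNN vs deep CNN vs RNN) is
preserved and the sizes are configurable.

**Semantic models** (`build_semantic_model()`): U-Net with `n_pool = 4`
levels and `base_filters = 8` doubling at each pooling level
(8-16-32-64-128), 50% dropout at the bottleneck, and a 1x1 four-class
head. Variants: residual blocks (identity shortcuts, 1x1 projections on
channel change), an RNN bottleneck (bidirectional vertical then horizontal
sweeps replacing the bottleneck convolutions), cSE / sSE / scSE excitation
blocks after every block, and `combined` (residual + RNN bottleneck +
scSE). The scSE combination is the element-wise maximum by default (the
excitation literature uses several combination rules; `scse_combine =
"add"` selects the additive one).

**Training** (`fit_patch_classifier()`, `fit_semantic_segmenter()`): Adam
with alpha 0.001, beta1 0.9, beta2 0.999, eps 1e-8; no learning-rate
schedule, no early stopping, no transfer learning; weights start from
He-scaled normals. Patch models minimise cross-entropy on exactly
class-balanced patch sets (one patch per boundary per eligible column plus
one background patch anchored at least 2 px from every boundary row — the
exclusion avoids label ambiguity from rounding). Semantic models minimise
cross-entropy plus Dice overlap loss on full images, with columns lacking
any annotation zeroed in the image and labelled vitreous in the mask, and a
50% random horizontal flip per image per epoch. The returned model is the
epoch checkpoint with the highest validation metric (patch accuracy /
validation Dice); ties resolve to the lower validation loss, which favours
the sharper of two equally accurate checkpoints. Runs are reproducible
given `seed`.

The Dice loss uses the squared-denominator (V-Net) form
$1 - \tfrac{1}{4}\sum_c (2\sum p g + s) / (\sum p^2 + \sum g^2 + s)$ with
smoothing $s = 1$ and equal class weights; at $s \to 0$ it is zero exactly
at the one-hot target (asserted in tests, including the closed-form value
0.6 for a uniform prediction on balanced classes).

## Numerical choices and tie-breaking

* **Coordinates.** 0-based, top-left origin everywhere a row position is a
  value (boundary rows, anchors); a boundary row is the first row of its
  lower region. Fractional rows round half-up — base `round()` is
  round-half-even, which would make rasterisation data-dependent.
* **Attenuation compensation.** `contrast_enhance()` computes
  $E(i,j) = I(i,j)^n / (2\sum_{k \ge i} I(k,j)^n + \varepsilon)$ with
  $n = 2$ by default, the tail sum starting at the pixel's own row, then
  rescales by the per-image maximum. The compensation family has several
  dialects (exponent, tail-sum start); both knobs are exposed. Note the
  direction of its effect: the deepest layer is always boosted (the
  compensated value tends to 1/2 at the bottom row), so the *ratio* of
  mean choroid to mean sclera intensity falls, while the Michelson
  contrast across the CSI — which is what determines boundary visibility
  in the probability maps — rises sharply; the tests assert the latter.
* **Sobel alignment.** A hard region step between rows $r-1$ and $r$
  produces a symmetric two-row Sobel plateau. Because the boundary row
  belongs to the lower region, the default `align = "lower"` averages
  adjacent response rows — a half-pixel shift onto the lower pixel — so
  the unique maximum lands on the boundary row; `align = "centered"`
  keeps the raw 3x3 response.
* **Graph search.** The solver computes exact forward and backward
  Dijkstra distances and then walks the optimal-path DAG preferring the
  smallest row, so equal-cost alternatives resolve deterministically to
  the upper path. The graph spans the full image height. The test suite
  checks path and cost equality against an independent dynamic-programming
  oracle on random maps, exact recovery of ideal staircase corridors, and
  the cost-monotonicity of the edge weights.
* **Boundary independence.** The three boundaries are searched
  independently; anatomical ordering of the three predicted paths is
  checked afterwards and violations raise a warning, not an error.
* **Patch borders.** Dense classification mirror-pads patches that
  overhang the image, avoiding artificial dark borders that would bias
  boundary probabilities at the edges.

## Problem sizes used by the tests and the acceptance script

The shipped verification runs are scaled so the whole suite trains real
networks from scratch on one CPU:

* the end-to-end semantic experiment uses 100 single-scan participants
  (80 training / 20 held-out) at 128 x 256 px with the full noise model,
  a standard U-Net (8 base filters, 4 pools) trained for 6 epochs, and
  evaluates inside a crop of (17, 42) columns — the study-format (100,
  250) crop scaled by the width ratio. On this task the held-out boundary
  errors sit well under 1.5 px (ILM, RPE) and 3.5 px (CSI), echoing the
  ordering ILM/RPE << CSI seen on clinical data;
* the exact-recovery fixture is a flat noise-free phantom (constant
  integer boundary rows): both pipelines, trained to saturation (120 / 60
  epochs), must reproduce the ground truth at every crop column. Flatness
  matters: on curved boundaries the patch classifier's horizontal context
  biases isolated single-column steps toward the neighbourhood-dominant
  row, and the Sobel response of a single-column step is an exact
  two-path tie — sub-pixel effects of the same order as the ~0.5 px
  boundary-error floor reported for these methods on real data, which an
  exactness test must not depend on;
* dataset-protocol arithmetic (300/240/60/294 scans, 1186 eligible
  columns, 4744 patches per scan) is checked with small phantom rasters,
  since it depends only on counts, splits and crops.

## Known limitations

* The engine is deliberately minimal: single-threaded CPU training,
  mini-batch looping in R, no data loaders. It trains the shipped
  architectures at phantom scale; it is not a general-purpose framework.
* Patch-based dense inference classifies H x W patches per scan and is far
  slower than a semantic forward pass, as expected for the method.
* The phantom's simplicity means validation Dice values above 99% are
  normal; they say nothing about clinical-grade accuracy.
* BMP input is not supported (no BMP reader in the supported stack);
  PNG and TIFF are.
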