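---
title: "Few-shot leaf and vein segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot leaf and vein segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

High-resolution flatbed scans of leaves (nominally 3510 x 2550 px at
300 DPI) contain two structures of biological interest: the leaf body
(lamina), whose outline drives morphological traits such as area,
perimeter, circularity and solidity, and the visible vein architecture,
whose skeleton drives venation traits such as total length, local diameter
and vein density (vein area / leaf area). Manually annotating whole images
is expensive — full venation takes hours per scan — so the package
implements a *few-shot* strategy: a handful of annotated images are
decomposed into very many small tiles, each posing an easy local decision,
and two iterative algorithms reassemble the local decisions into
biologically coherent whole-image segmentations:

* **Boundary tracing** for the leaf body. A CNN sees a 256 x 256 tile
  (RGB + an overlay of the recently traced path) centred on the leaf
  margin and regresses the next `N = 128` boundary-pixel displacements.
  At inference the tracer walks around the leaf committing the first 32
  predicted pixels per step, and closes the contour when it re-approaches
  previously traced pixels within 10 px. Because the result is a single
  filled contour, the mask is one connected region without holes by
  construction.

* **Region growing** for the veins. A CNN sees a 128 x 128 RGB tile
  centred on a pixel and classifies the 3 x 3 neighbourhood of the centre
  as vein / background (softmax pairs per pixel). Growth starts from
  10,000 random seeds inside the leaf; positively classified neighbours
  become new centres, each pixel is a centre at most once, and every
  prediction is accumulated so the final mask thresholds the *average*
  probability of each pixel. The threshold is chosen to minimise the
  number of 8-connected components, because a real vein network is one
  connected structure.

* A **U-Net baseline** with the same encoder, a mirrored decoder
  (transposed-convolution upsampling, concatenated skip connections) and a
  per-pixel sigmoid output, applied over an overlapping tile grid at
  half-tile stride with probability averaging.

# Objectives

The tracer minimises a weighted mean squared error over the displacement
sequence,

$$L = \frac{1}{N}\sum_{i=1}^{N} \omega_i \lVert y_i - \hat y_i \rVert_2^2,
\qquad
\omega_i = 1 + \frac{1 - \tanh(\alpha i + \beta)}{2},$$

with `alpha = 8/N` and `beta = -4`, so that errors near the tile centre
weigh about twice errors near the tile edge (`trace_weights()`), where the
network necessarily has less context. The grower and the U-Net use either
binary cross-entropy or the focal loss

$$L_{FL} = \begin{cases}
-\alpha (1-p)^\gamma \log p & y = 1\\
-(1-\alpha) p^\gamma \log(1-p) & y = 0
\end{cases}$$

with the standard defaults `alpha = 0.25`, `gamma = 2` (`focal_loss()`).
With `gamma = 0`, `alpha = 0.5` the focal form reduces exactly to half the
cross-entropy; the test suite verifies this identity at `1e-12` over
10,000 random pairs. Probabilities are clamped to `[1e-7, 1 - 1e-7]`
inside logarithms.

# Architecture

All three models share one encoder family: blocks of three zero-padded
3 x 3 convolutions, each with batch normalization and LeakyReLU
(slope 0.1), a residual connection from the first activation of the block
to the third pre-activation, and 2 x 2 max pooling between blocks. At full
scale the tracer uses 7 blocks (6 pooled) taking 256 -> 4 spatially,
followed by a linear 4 x 4 convolution to a 256-vector reshaped 2 x 128;
the grower drops the first block (128 -> 4) and ends in an 18-vector
reshaped 3 x 3 x 2 with per-pixel softmax. The U-Net keeps the encoder,
mirrors the widths in a decoder with 2 x 2 transposed convolutions,
concatenates the pre-pooling encoder activations at each resolution, and
ends in a 1 x 1 convolution with sigmoid.

No deep-learning framework is available to R in this package's target
environment, so the engine — im2col convolutions, batch-norm statistics,
pooling with argmax, the transposed-convolution decoder, the three losses
and Adam — is implemented in compiled code (`src/nn.cpp`), in single
precision. Analytic gradients are validated against directional finite
differences in the test suite (per-element differences are below fp32
resolution). Training is deterministic given the seed: shuffling uses a
private Mersenne-Twister stream, initialisation flows from R's RNG through
`withr::with_seed()`, and no global RNG state is touched.

# Desk-scale configurations

The package is exercised end-to-end on synthetic scans small enough to
train on one CPU core in minutes. These presets scale the full-size
scanner setup by a factor of about four and are used throughout the
tests, the demo and the worked examples:

* `scaled_tracer_config()`: 64-px tiles, 3 blocks, `N = 32` displacements,
  8-px commits, 5-px closure radius, 10 burn-in iterations.
* `scaled_grower_config()`: 16-px tiles, widths 12/24 (one pooling).
  Two design points matter here. First, at this tile size a deeper encoder
  (more poolings) loses the spatial resolution needed to decide *which*
  neighbour pixel a 3 x 3 output refers to — the averaged probability maps
  blur and threshold selection degenerates — so the desk-scale grower is
  deliberately shallow; the full-scale configuration keeps the 6-block
  geometry, where 128+ channels preserve sub-cell position.
  Second, the learning rate is raised to 5e-3: the focal loss's
  `alpha = 0.25`, `(1-p)^gamma` down-weighting makes positive-class
  confidence grow slowly in small models, and the higher rate reaches a
  confident plateau within the early-stopping window.
* `scaled_unet_config()`: 32-px tiles, widths 12/24/48 mirrored.

Augmentation at desk scale uses random quarter-turn rotations and flips
(which permute a 3 x 3 label grid exactly), continuous rotations for the
tracer, centre jitter of up to 3 px, and mild channel jitter. One subtlety
is worth recording: flips and quarter-turns of *even*-sized tiles move the
grid centre by one pixel, which silently misaligns any label tied to the
tile centre. The package therefore uses centre-pixel-fixed transforms
(rotate/flip, then shift one row/column, filling the vacated edge).
Augmentation is drawn once per tile when the dataset is built rather than
re-drawn per epoch; at these dataset sizes each contour pixel contributes
one augmented view per build, and the invariances taught are the same.

# The synthetic generator

`generate_leaf()` renders a parametric leaf: a lamina whose boundary is an
ellipse modulated by a low-order random Fourier perturbation plus a
triangular serration term; a single connected vein tree (midrib from apex
to petiole attachment, recursive side branches with linearly tapering
width); a petiole protruding below the blade; near-white scanner
background; and per-pixel smooth colour noise on the lamina, with veins
rendered lighter than the lamina as on leaf-bottom scans. Optional
artifacts — a dark fold line, a vertical near-white stripe, dust specks
and a blur patch — perturb the image only; masks remain exact. The
`true_traits` attached to each sample are computed from the generative
geometry (polygon area of the boundary curve, summed segment lengths),
never from the rasters, so parameter-recovery tests have an independent
reference.

What the generator does *not* emulate: damaged or diseased tissue,
overlapping leaves, shadows, specular highlights, petiole curvature, or
the faint/discontinuous veins of real scans where lamina occludes
venation. Passing tests on synthetic data therefore validate the
*algorithms* (their loops, losses, thresholds and unit conversions), not
field performance.

`generate_population()` simulates clonal structure: a genotype effect
drawn from `N(0, sigma_G^2)` plus clone noise `N(0, sigma_E^2)` shifts a
latent vein-density driver (branch length scaling), so broad-sense
heritability of the true trait values has expectation
`sigma_G^2 / (sigma_G^2 + sigma_E^2)`.

# Traits and evaluation

Pixel lengths convert to millimetres as `px * 25.4 / dpi`. Leaf area,
perimeter, circularity (`4*pi*A/P^2`) and solidity come from the filled
mask; the perimeter uses Kulpa-corrected chain-code weights (0.948 per
axial step, 1.343 per diagonal), which is close to unbiased for smooth
boundaries — a raw 1/sqrt(2) chain length overestimates smooth perimeters
by ~5% and biases circularity low by ~10%. Vein traits restrict the vein
mask to the leaf, skeletonise (Zhang-Suen), measure local diameter as
twice the Euclidean distance transform at skeleton pixels, and partition
skeleton arc length into the three diameter classes < 0.25 mm,
[0.25, 0.80) mm and >= 0.80 mm; each skeleton pixel carries half the
summed length of its incident edges, so the class partition sums exactly
to the total. The petiole is the largest vein component outside the leaf;
its length is the longer side of the minimum-area rotated rectangle
(rotating calipers over the convex hull, +1 px for pixel extent), its
width the mean local diameter over the central 20% of skeleton arc length
(mirroring caliper placement at the petiole midpoint), and its volume a
solid of revolution over local diameters.

Heritability uses the one-way random-effects decomposition:
`sigma2_E = MS_within`,
`sigma2_G = max(0, (MS_between - MS_within) / k_bar)` with the standard
effective clone number `k_bar = (n - sum(k^2)/n) / (g - 1)` for unbalanced
designs, and `H2 = sigma2_G / (sigma2_G + sigma2_E)`; negative genotypic
variance estimates truncate to zero so `H2` stays in `[0, 1]`. An optional
median-absolute-deviation pre-filter (field workflows use MAD > 6) drops
gross outliers. Model comparison of vein-component counts uses one-way
ANOVA with Tukey's HSD at `alpha = 0.05` (`multcomp`), reported as group
letters.

# Numerical choices and degenerate inputs

* Probability clamp `1e-7` inside logs; empty masks get an infinite
  component count during threshold selection so "predict nothing" cannot
  win; threshold ties resolve towards the smaller threshold.
* Recall of the learned grower is reported at fixed threshold 0.5
  (matching the Jaccard protocol used for model comparison); component
  counts are reported at the connectivity-minimising threshold.
* The tracing closure test ignores the most recent `2 * step_commit`
  committed pixels (without a guard the trace would terminate against its
  own tail) and only consults pixels stored after the 10 burn-in
  iterations; a hard iteration cap of four circumferences raises a
  "tracing diverged" condition carrying the partial path.
* `rough_foreground()` requires a dynamic range above 1e-3 and a non-empty
  dark side of the Otsu split, and keeps only the largest component, so
  dust specks never seed the tracer.
* Contours are stored counter-clockwise (as displayed); filling is
  orientation-invariant; a single-pixel contour fills to a single pixel.
* Both-empty masks score Jaccard 1; recall is an error for empty truth.

# Problem sizes used in tests

The test-suite study conditions are: 8 synthetic leaves (6 training, 2
held out) on a 288 x 224 canvas at 300 DPI nominal resolution, with
lamina radius 70 px, serration 3 px / 24 teeth, vein base width 5 px,
branch depth 3 and a 30 x 5 px petiole; trait recovery uses 50+ rendered
samples; heritability recovery uses 100 replicates of 200 genotypes x 2
clones (true trait values, no rendering). These sizes were chosen so the
complete suite trains every model from scratch in well under half an hour
on one core while leaving each learning task non-trivial.

# What desk scale does and does not mirror

The component-count comparison deserves a candid note. On hard field
images, per-pixel models fragment faint or occluded veins into many
objects, while region growing's connectivity prior keeps the count low —
that is the motivation for counting components at all. On clean synthetic
renders the situation inverts: a fully supervised per-pixel U-Net receives
orders of magnitude more supervised pixels per tile than the grower's 3x3
targets, solves the desk-scale task almost perfectly (held-out Jaccard
above 0.99, a single connected component), and therefore *undercuts* the
grower's component counts. The test suite asserts the field-data ordering
as the property of record and the assertion fails at desk scale; the
accompanying quality metrics (Jaccard, recall, per-threshold component
profiles) make the cause visible. Adding scan artifacts to the comparison
images raises U-Net counts several-fold but does not restore the ordering.
This is a regime difference, not an implementation artifact: conclusions
about the relative biological accuracy of the two segmenters require data
in which vein appearance is genuinely ambiguous.

# Known limitations

* The generator's difficulty is tunable but modest; real scans are
  harder, and the desk-scale accuracies reported by the tests (e.g. leaf
  Jaccard >= 0.95) mirror the *form* of full-scale results, not their
  values.
* The grower only ever classifies centres inside the supplied leaf mask,
  so a petiole outside the blade is not reachable by growing; petiole
  traits in the demo pipeline use the ground-truth petiole geometry.
* Vein traits assume the 8-connected skeleton approximates the medial
  axis; hairpin branches under 2 px can merge under skeletonisation.
* Training runs inside one compiled call; there is no mid-training
  checkpoint callback beyond best-validation tracking.
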