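---
title: "Dual-branch lightweight U-Net segmentation of hyperspectral vegetation scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-branch lightweight U-Net segmentation of hyperspectral vegetation scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsiseg)
```

## The problem

Airborne hyperspectral imagery records a full visible-to-near-infrared
reflectance spectrum (here 400–1000 nm) at every pixel, which in principle
identifies land cover down to the species level. In practice two confusions
dominate: the *same* cover type varies spectrally across a scene
(illumination, canopy structure), and *different* cover types can share
nearly identical spectra. Pixel-wise classifiers built on spectra alone
therefore misclassify along class boundaries and among spectrally similar
vegetation classes.

`hsiseg` implements a dual-input encoder–decoder segmentation network that
attacks both problems at once:

* the spectral input is the cube reduced to **6 principal-component
  channels**, concentrating almost all spectral variance;
* the artificial input stacks **six hand-crafted feature channels** —
  NDVI, four gray-level co-occurrence (GLCM) texture statistics, and the
  Sobel edge magnitude — that carry spatial structure and vegetation
  physiology the raw spectra express only weakly;
* both feed a **U-Net whose convolutions are replaced by residual
  depthwise-separable feature-extraction modules**, cutting parameters
  roughly by the kernel area while the identity shortcuts keep gradients
  flowing.

Everything — forward pass, hand-derived backpropagation, Adam — is
implemented in the package (compiled kernels for the spatial primitives,
BLAS for the pointwise convolutions), so the method is fully inspectable
and testable end to end on synthetic scenes.

## The model

### PCA band reduction

Pixels are flattened to a samples × bands matrix, standardized per band
(z-scored), and the covariance of the standardized data — the band
correlation matrix — is eigendecomposed. The top-6 eigenvectors give the
6-channel spectral input. Standardization follows the method's description
of the reduction step; whether a covariance- or correlation-matrix PCA was
used originally is not stated, and we read "standardizing" literally. Each
eigenvector's sign is fixed so its largest-magnitude loading is positive;
eigendecompositions are otherwise sign-ambiguous and this makes every
downstream raster deterministic.

### Artificial features

The six channels, in canonical order:

1. **NDVI** = (NIR − R)/(NIR + R), with NIR and R picked as the bands
   nearest 800 nm and 670 nm (configurable; the match is refused beyond a
   50 nm tolerance rather than silently wrong). Pixels with NIR + R = 0
   get 0, the rock/bare-soil convention. NDVI is positive over green
   vegetation (the red edge), negative over water.
2. – 5. **GLCM homogeneity, mean, dissimilarity, entropy** over a 3 × 3
   sliding window. The source image is the first principal component
   rescaled to [0, 1], quantized to 16 gray levels; symmetric co-occurrence
   counts are accumulated over four offsets (0,1), (1,0), (1,1), (1,−1).
   The window size is the method's stated choice; gray levels and offsets
   are not stated and we use common texture-analysis defaults, both
   configurable. One listing of the statistics says "similarity"; every
   other occurrence (including the computation sentence and the figure)
   says dissimilarity, which is what we implement.
6. **Sobel gradient magnitude** of the same PC1 image, using the two
   printed 3 × 3 factors applied as cross-correlation (the factors are
   directional difference masks; no 180° flip). One channel (the
   magnitude), so the branch totals 1 + 4 + 1 = 6 channels.

Every sliding window uses symmetric reflect padding, so feature rasters
align pixel-for-pixel with the cube and no border is dropped. Each channel
is min–max normalized to [0, 1] with the affine map recorded.

### The feature-extraction module

Each module is: 3 × 3 depthwise convolution (reflect "same" padding) →
1 × 1 pointwise convolution → batch normalization → identity shortcut
(input added, only when input and output widths match) → h-swish,
`x · ReLU6(x + 3) / 6`. Parameter count is
`9·C_in + C_in·C_out + 2·C_out`, independent of the shortcut — identity
shortcuts are parameter-free, which the tests assert for the full networks.
The original figure's internal ordering (whether a batch norm follows each
convolution) is not fully legible; we fix one batch norm after the
pointwise convolution, with the activation after the residual add, and
note this as our choice rather than a claim about the original layout.

### Topologies

*Single branch*: 5 encoder levels of two modules each (the first module of
a level changes width, so only the second carries a shortcut), 2 × 2 max
pooling between levels; a mirrored decoder with 2 × upsampling (bilinear +
pointwise width reduction; transposed-style nearest mode available), skip
concatenation, two modules per level; a final 1 × 1 convolution to
per-pixel class logits. Default widths [32, 64, 128, 256, 512] — the
original widths are unstated, so absolute parameter totals are not
reconstructible; the *relations* (separable < plain convolution; residual
toggle changes nothing; dual > single) are what the package asserts.

*Dual branch*: two structurally identical encoders with independent
weights (weight sharing is unstated; independence is the weaker
assumption). At every level the two branches' pre-pool feature maps are
concatenated and reduced back to the level width by a pointwise
convolution; these fused tensors form the skip connections and the
bottleneck of a single shared decoder.

*Plain U-Net baseline*: same topology with ordinary 3 × 3 convolutions,
batch norm and ReLU — the comparison baseline for the architecture
ablation. Other published baselines of the original comparison are out of
scope.

### Loss and training

Per-pixel classification is treated as independent binary problems: one
sigmoid per class, binary cross-entropy averaged over valid pixels and
classes (computed in the numerically stable logit form), argmax fusion at
prediction. A softmax cross-entropy alternative sits behind a flag, since
"soft classifier" admits either reading. Unlabeled pixels (id 0) and
reflection-padded tile margins are masked out of loss and metrics; how
background was treated originally is unstated.

The optimizer is Adam (unstated originally; the de facto U-Net default),
initial learning rate 1e-4, batch of 4 tiles, up to 600 epochs — that is
the full-scale protocol and the `train_config()` default (with 30 epochs
as the desk-scale default). The original protocol sentence describes an
epoch-100 learning-rate step whose target value equals the initial value;
we default to a constant schedule and provide the ×0.1 step behind
`lr_schedule = "step"`. ImageNet pre-training is inapplicable to
6-channel dual inputs; initialization is He-normal from the run seed.

Gradient correctness is not assumed: the test-suite checks every analytic
gradient of the full dual-branch network against central finite
differences (tolerance 1e-4), and the module/loss formulas against
brute-force oracles.

## The synthetic scene generator

Scenes emulate the statistical structure the method assumes, not any real
radiative transfer:

* **Endmembers**: one smooth spectrum per class in [0, 1], built from a
  kind-specific archetype (vegetation: chlorophyll absorption near 670 nm,
  green bump, red-edge sigmoid of 30 nm scale to a NIR plateau; water:
  low, decaying toward NIR; bare soil: rising ramp; built: bright, flat)
  plus seeded Gaussian bumps. Classes must clear a pairwise spectral-angle
  floor (default 0.05 rad) or generation fails explicitly. The red-edge
  scale matters: adjacent-band correlation of rendered cubes stays ≥ 0.9
  at the default 32-band spacing, but a spectral feature narrower than the
  band gap would (correctly) decorrelate neighbouring bands, as it does if
  scenes are generated with very few bands.
* **Class map**: per-class Gaussian-smoothed noise fields (length scale
  `blob_smoothness`, default 32 px), per-pixel argmax — irregular,
  interlocking contiguous regions rather than Voronoi polygons, so edge
  features are genuinely exercised. Every class id is guaranteed present;
  0 is reserved for "unlabeled".
* **Rendering**: pixel spectrum = endmember × (1 + class-dependent
  multiplicative texture field, amplitude 0.05) + iid Gaussian noise
  (sigma 0.01), clipped to [0, 1]. The texture is multiplicative so it
  survives PCA and is visible to GLCM; each class has its own correlation
  length so texture carries class information. One global seed fans out to
  per-stage child seeds, so spectra, map and rendering are independently
  reproducible.

What the generator does **not** emulate: mixed pixels and abundance
gradients, atmospheric and illumination artefacts, sensor striping,
class-imbalance extremes, or the sheer class count of real agricultural
mosaics. Passing the end-to-end test therefore shows the pipeline learns
and generalizes on well-posed scenes — it does not certify accuracy on
real imagery.

## Desk-scale problem sizes

The packaged experiments and tests run on one CPU, so the full-scale
protocol is scaled down as the package's standard desk configuration:
256 × 256 × 32 scenes with 5 classes, 64-pixel tiles (full-scale runs use
512), an 8:2 tile split, ≤ 30 epochs, and learning rate 1e-3 for these
short runs — compressing a 600-epoch schedule into 30 epochs while keeping
the full-scale protocol default (1e-4) in `train_config()`. Under this
configuration the dual-branch model reaches ≈ 97 % held-out pixel accuracy
(the end-to-end test asserts ≥ 95 %).

## Numerical choices

* Reflect (mirror, edge-excluded) padding everywhere; all resampling
  stages are left-right/up-down symmetric, verified by a kernel-mirrored
  flip-equivariance test.
* Bilinear 2 × upsampling uses half-pixel centres; its backward pass is
  the exact adjoint (finite-difference checked).
* BCE is computed from logits as `max(z,0) − zy + log(1+exp(−|z|))`; no
  probability ever reaches 0 or 1.
* Batch-norm: batch statistics during training (momentum 0.1 running
  estimates, eps 1e-5), running statistics at inference; an epoch-level
  best-validation checkpoint keeps weights *and* running statistics.
* Argmax ties (exactly equal logits) break toward the lower class id.
* Zero-variance bands get scale 1 with a warning instead of dividing by
  zero; constant images quantize to gray level 0; empty masks are errors,
  never NaN.
* `split_tiles` follows ⌈0.8·n⌉ exactly, so 4 tiles split 4/0 — callers
  wanting a non-empty test set need ≥ 5 tiles (the defaults give 16).

## Limitations

* Training is CPU-bound R + BLAS; full-scale 512-pixel tiles and
  600-epoch schedules are possible but slow — the architecture, not the
  engine, is the point.
* The per-class-sigmoid loss ignores class exclusivity during training;
  argmax imposes it only at prediction (the softmax flag trades this off).
* Group-level metrics assume the class scheme's two-level hierarchy is
  correct; there is no fuzzy matching.
* ENVI I/O covers float BSQ/BIL/BIP with wavelength metadata — the subset
  the pipeline needs — not the full header dialect; projected/geocoded
  rasters are out of scope.
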