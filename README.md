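# hsiseg

Pixel-wise vegetation and land-cover classification of hyperspectral
imagery with a dual-input lightweight U-Net, implemented natively in R
(compiled kernels for the spatial primitives, BLAS for the pointwise
convolutions — no external deep-learning framework).

## Who this is for

Remote-sensing and vegetation-mapping researchers who want an inspectable,
fully tested implementation of a dual-branch feature-fusion segmentation
network for hyperspectral cubes — including readers who have no access to
large airborne datasets: a synthetic labelled-scene generator reproduces
the statistical structure the method assumes (smooth inter-band-correlated
class spectra, red-edge vegetation, water with NIR below red, class-
dependent texture), so the whole pipeline trains and validates on a
laptop CPU.

## The method

A hyperspectral cube `M` (H × W pixels × B bands, 400–1000 nm) is reduced
two ways, and both reductions feed one network:

* **Spectral branch** — standardized PCA of the pixels × bands matrix;
  the top 6 eigenvectors of the band correlation matrix give an
  H × W × 6 score image.
* **Artificial branch** — six hand-crafted channels, H × W × 6:
  NDVI = (NIR − R)/(NIR + R); GLCM homogeneity, mean, dissimilarity and
  entropy over a 3 × 3 sliding window of the first principal component
  (16 gray levels, 4 symmetric offsets); and the Sobel gradient magnitude
  of the same image.

The backbone replaces every U-Net convolution with a **feature-extraction
module**: 3 × 3 depthwise convolution → 1 × 1 pointwise convolution →
batch norm → identity residual shortcut (when widths match) → h-swish
(`x·ReLU6(x+3)/6`). A module costs `9·C_in + C_in·C_out + 2·C_out`
parameters versus `9·C_in·C_out` for the convolution it replaces, and the
shortcut adds none — both facts are asserted as tests. Two structurally
identical encoders (independent weights) process the two inputs; at each
of the 5 levels their pre-pool features are concatenated and reduced by a
1 × 1 convolution into the skip tensor of a single shared decoder; a final
1 × 1 convolution yields per-pixel class logits. Training treats each
class as a binary problem (per-class sigmoid + binary cross-entropy,
unlabeled pixels masked), optimized with Adam on 8:2 tile splits;
prediction fuses the per-class probabilities by argmax and mosaics tiles
back to scene extent. Metrics are confusion-matrix based: per-class
precision/recall/F1, overall accuracy, and F1 over first-level class
groups (e.g. Forest, Waters).

## Worked example

```r
library(hsiseg)

# 1. a labelled synthetic scene: 5 classes, 256 x 256 pixels, 32 bands
scene <- simulate_scene(scene_spec(n_classes = 5, seed = 42))

# 2. spectral input: 6 principal-component channels
pca <- fit_pca(scene$cube, k = 6)

# 3. artificial input: NDVI + 4 GLCM textures + Sobel magnitude
feats <- build_artificial_stack(scene$cube)

# 4. tile, split 8:2, build and train the dual-branch network
tiles <- tile_scene(apply_pca(scene$cube, pca), feats, scene$labels, tile = 64)
split <- split_tiles(tiles, ratio = 0.8, seed = 42)
model <- build_dual_branch(
  net_config(in_channels = c(6, 6), n_classes = 5, branch_mode = "dual"),
  seed = 42)
fit <- train_model(model, split$train,
                   train_config(max_epochs = 30, lr = 1e-3, seed = 42),
                   validation = split$test)

# 5. held-out metrics
pred <- predict_labels(fit, split$test)
truth <- label_map(local({
  m <- mosaic_tiles(split$test, lapply(split$test$tiles, `[[`, "labels"))
  m[is.na(m)] <- 0L; round(m)
}), scene$labels$scheme)
metrics_report(truth, pred$labels)
```

Printed output (about four minutes on one CPU):

```
<spectral_cube> 256 x 256 pixels, 32 bands (400-1000 nm)
<label_map> 256 x 256, 5 classes (vegetation_1, water_2, bare_3, built_4, vegetation_5)
<pca_model> 32 bands -> 6 components (99.7% variance)
<feature_stack> 256 x 256 x 6 [ndvi, glcm_homogeneity, glcm_mean, glcm_dissimilarity, glcm_entropy, sobel_magnitude]
<hsiseg_model> dual-branch depthwise-separable U-Net, 5 levels [32, 64, 128, 256, 512], 5 classes, 2,231,537 parameters
<hsiseg_fit> 30 epochs; final loss 0.1885, accuracy 0.9437
<metrics_report> overall accuracy 83.21%, macro P 71.16% R 66.84% F1 68.74%
  group F1 (%): Vegetation 97.61, Waters 98.50, Bare areas 87.56, Buildings 98.75
```

Six PCA channels carry 99.7 % of the spectral variance; the dual-branch
network (2.2 M parameters — under a third of the 7.2 M plain-convolution
U-Net at the same widths) separates the first-level groups almost
perfectly (group F1 87–99 %). This seed's two *vegetation* secondary
classes are spectrally similar and confuse each other on held-out tiles —
the classic same-spectrum/different-object ambiguity, invisible at the
group level but visible in the 83 % overall accuracy; easier seeds reach
97 % (see the reproduction script below).
`plot_training_history(fit)`, `plot_label_map(pred)` and
`run_experiment("e1" | "e2" | "e3")` reproduce the training-curve,
prediction-map and ablation comparisons at desk scale. A thin CLI wraps
the same functions: `exec/hsiseg simulate|features|train|eval|experiment`.

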