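# NDVI, GLCM textures and Sobel edges.

test_that("NDVI follows its closed forms and conventions", {
  mk <- function(nir, red) spectral_cube(
    array(c(matrix(red, 2, 2), matrix(nir, 2, 2)), c(2, 2, 2)),
    wavelengths = c(670, 800))
  expect_equal(compute_ndvi(mk(0.8, 0.2))[1, 1], 0.6)
  expect_equal(compute_ndvi(mk(0.5, 0.5))[1, 1], 0)
  expect_equal(compute_ndvi(mk(0, 0))[1, 1], 0)  # rock / bare-soil convention
})

test_that("NDVI is bounded and scale-invariant on arbitrary non-negative cubes", {
  for (seed in 1:3) {
    cube <- withr::with_seed(seed, spectral_cube(
      array(runif(16 * 16 * 8, 0, 2), c(16, 16, 8)),
      wavelengths = seq(450, 950, length.out = 8)))
    nd <- compute_ndvi(cube)
    expect_true(all(nd >= -1 & nd <= 1))
    scaled <- spectral_cube(cube$data * 2.5, cube$wavelengths)
    expect_equal(compute_ndvi(scaled), nd, tolerance = 1e-12)
  }
})

test_that("gray quantization bins linearly and handles constants", {
  expect_true(all(quantize_gray(matrix(0.7, 4, 4)) == 0L))
  ramp <- matrix(seq(0, 1, length.out = 8), 1, 8)
  q <- quantize_gray(ramp, levels = 4)
  expect_identical(as.vector(q), c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  r <- matrix(runif(100), 10, 10)
  expect_lt(max(quantize_gray(r, 16)), 16)
})

test_that("single-window GLCM features match hand enumeration and the brute-force oracle", {
  # constant window: single co-occurrence cell
  f <- glcm_window_features(matrix(3L, 3, 3), levels = 16)
  expect_equal(unname(f), c(1, 3, 0, 0))
  # 3x3 checkerboard of {0,1}, horizontal offset only: all 6 pairs are (0,1)
  # or (1,0): P = [[0,.5],[.5,0]]
  cb <- matrix(c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, 0L), 3, 3)
  f <- glcm_window_features(cb, levels = 2, offsets = cbind(0L, 1L))
  expect_equal(unname(f["homogeneity"]), 0.5)
  expect_equal(unname(f["mean"]), 0.5)
  expect_equal(unname(f["dissimilarity"]), 1)
  expect_equal(unname(f["entropy"]), -2 * 0.5 * log(0.5))
  # random windows vs the naive pair-counting oracle
  for (seed in 1:4) {
    win <- withr::with_seed(seed, matrix(sample(0:7, 25, TRUE), 5, 5))
    got <- glcm_window_features(win, levels = 8)
    want <- glcm_oracle_window(win, levels = 8, offsets = glcm_default_offsets())
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(glcm_window_features(matrix(0L, 1, 1)), "no valid pixel pairs")
})

test_that("sliding GLCM maps equal the per-pixel brute-force oracle exactly", {
  for (seed in 1:2) {
    img <- withr::with_seed(seed, matrix(runif(16 * 16), 16, 16))
    q <- quantize_gray(img, 8)
    got <- glcm_map(img, window = 3, levels = 8)
    want <- glcm_oracle_map(q, window = 3, levels = 8,
                            offsets = glcm_default_offsets())
    expect_lt(max(abs(got - want)), 1e-12)
    expect_identical(got, glcm_map(img, window = 3, levels = 8))
  }
  cst <- glcm_map(matrix(1, 8, 8))
  expect_true(all(cst[, , "homogeneity"] == 1))
  expect_true(all(cst[, , "dissimilarity"] == 0))
  expect_true(all(cst[, , "entropy"] == 0))
  expect_error(glcm_map(matrix(1, 8, 8), window = 4), "odd")
})

test_that("Sobel magnitude matches the double-loop oracle and its closed forms", {
  expect_true(all(sobel_edges(matrix(5, 9, 9)) == 0))
  # unit column ramp: interior gx = 8, gy = 0
  ramp <- matrix(rep(1:12, each = 10), 10, 12)
  o <- sobel_oracle(ramp)
  expect_true(all(o$gx[2:9, 2:11] == 8))
  expect_true(all(o$gy[2:9, 2:11] == 0))
  expect_equal(sobel_edges(ramp), o$magnitude, tolerance = 1e-12)
  for (seed in 1:3) {
    img <- withr::with_seed(seed, matrix(runif(144), 12, 12))
    expect_lt(max(abs(sobel_edges(img) - sobel_oracle(img)$magnitude)), 1e-12)
  }
  # 90-degree rotation swaps the two gradient components
  img <- withr::with_seed(9, matrix(runif(100), 10, 10))
  rot <- t(img[nrow(img):1, ])
  o1 <- sobel_oracle(img); o2 <- sobel_oracle(rot)
  expect_equal(sort(abs(as.vector(o1$gx))), sort(abs(as.vector(o2$gy))),
               tolerance = 1e-12)
})

test_that("the artificial stack has the canonical six channels, normalized and recorded", {
  sc <- tiny_scene(seed = 17)
  fs <- build_artificial_stack(sc$cube)
  expect_identical(dim(fs$data), c(64L, 64L, 6L))
  expect_identical(fs$channel_names[1], "ndvi")
  expect_true(all(fs$data >= 0 & fs$data <= 1))
  expect_true(all(is.finite(fs$data)))
  # channel 0 equals raw NDVI up to the recorded affine map
  nd <- compute_ndvi(sc$cube)
  rec <- fs$normalization[1, ]
  expect_equal(fs$data[, , 1] * (rec$max - rec$min) + rec$min, nd,
               tolerance = 1e-12)
})

test_that("per-class mean NDVI separates vegetation from water on a clean scene", {
  spec <- scene_spec(64, 64, n_bands = 16, n_classes = 4,
                     class_kinds = c("vegetation", "water", "vegetation", "water"),
                     noise_sigma = 0, texture_amplitude = 0, seed = 19)
  sc <- simulate_scene(spec)
  fs <- build_artificial_stack(sc$cube)
  nd <- compute_ndvi(sc$cube)
  for (ci in 1:4) {
    m <- mean(nd[sc$labels$labels == ci])
    if (spec$class_kinds[ci] == "vegetation") expect_gt(m, 0) else expect_lt(m, 0)
  }
})
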