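# PCA band reduction, tiling and splitting.

random_cube <- function(seed, H = 50, W = 50, B = 8) {
  withr::with_seed(seed, {
    # correlated bands: latent factors + noise
    F <- matrix(rnorm(H * W * 3), H * W, 3)
    L <- matrix(rnorm(3 * B), 3, B)
    X <- F %*% L + matrix(rnorm(H * W * B, sd = 0.3), H * W, B)
    spectral_cube(array(X, c(H, W, B)), wavelengths = seq(400, 1000, length.out = B))
  })
}

test_that("rank-1 data concentrates all variance in the first component", {
  b1 <- matrix(runif(16 * 16), 16, 16)
  cube <- spectral_cube(array(c(b1, 2 * b1), c(16, 16, 2)), c(500, 600))
  m <- fit_pca(cube, k = 2)
  expect_equal(m$explained_variance_ratio[1], 1, tolerance = 1e-10)
  expect_equal(m$explained_variance_ratio[2], 0, tolerance = 1e-10)
})

test_that("fitted components match an independent PCA oracle up to sign", {
  for (seed in c(11, 12)) {
    cube <- random_cube(seed)
    m <- fit_pca(cube, k = 8)
    X <- matrix(cube$data, 2500, 8)
    oracle <- prcomp(X, center = TRUE, scale. = TRUE)
    expect_equal(m$eigenvalues, unname(oracle$sdev^2), tolerance = 1e-8)
    for (j in 1:8) {
      dot <- abs(sum(m$components[, j] * oracle$rotation[, j]))
      expect_equal(dot, 1, tolerance = 1e-8)
    }
    expect_true(all(diff(m$explained_variance_ratio) <= 1e-12))
    expect_true(all(m$explained_variance_ratio >= 0 &
                      m$explained_variance_ratio <= 1))
    # orthonormal loadings
    G <- crossprod(m$components)
    expect_lt(max(abs(G - diag(8))), 1e-8)
  }
})

test_that("k = B projection then back-projection is the identity on standardized data", {
  cube <- random_cube(13)
  m <- fit_pca(cube, k = 8)
  X <- matrix(cube$data, 2500, 8)
  Z <- scale(X)
  S <- matrix(apply_pca(cube, m)$data, 2500, 8)
  back <- S %*% t(m$components)
  expect_lt(max(abs(back - Z)), 1e-6)
})

test_that("scores are centred and their variance equals the kept eigenvalues", {
  cube <- random_cube(14)
  m <- fit_pca(cube, k = 4)
  S <- matrix(apply_pca(cube, m)$data, 2500, 4)
  expect_lt(max(abs(colMeans(S))), 1e-8)
  expect_equal(sum(apply(S, 2, function(x) sum(x^2) / (length(x) - 1))),
               sum(m$eigenvalues), tolerance = 1e-8)
  # oracle projection by explicit matrix multiply
  X <- matrix(cube$data, 2500, 8)
  Z <- sweep(sweep(X, 2, m$mean), 2, m$scale, "/")
  expect_equal(S, unname(Z %*% m$components), tolerance = 1e-10)
})

test_that("constant bands are tolerated with a warning, zero-variance input gives zero scores", {
  arr <- array(runif(100 * 3), c(10, 10, 3))
  arr[, , 2] <- 0.5
  cube <- spectral_cube(arr, c(400, 500, 600))
  expect_warning(m <- fit_pca(cube, k = 2), "constant band")
  expect_true(all(is.finite(m$components)))
  flat <- spectral_cube(array(0.7, c(10, 10, 3)), c(400, 500, 600))
  expect_warning(mf <- fit_pca(flat, k = 2), "constant")
  S <- apply_pca(flat, mf)$data
  expect_true(all(S == 0))
  expect_error(apply_pca(random_cube(1), m), "bands")
})

test_that("tiling partitions the scene and mosaicking inverts it", {
  sc <- tiny_scene(seed = 8, size = 64)
  pcac <- apply_pca(sc$cube, fit_pca(sc$cube, 6))
  fs <- build_artificial_stack(sc$cube)
  tiles <- tile_scene(pcac, fs, sc$labels, tile = 32)
  expect_length(tiles$tiles, 4)
  # origins reconstruct a partition: every pixel covered exactly once
  cover <- matrix(0, 64, 64)
  for (t in tiles$tiles) {
    rows <- t$origin["row"]:(t$origin["row"] + t$valid_h - 1)
    cols <- t$origin["col"]:(t$origin["col"] + t$valid_w - 1)
    cover[rows, cols] <- cover[rows, cols] + 1
  }
  expect_true(all(cover == 1))
  # mosaic of tile labels reproduces the scene labels exactly
  mos <- mosaic_tiles(tiles, lapply(tiles$tiles, `[[`, "labels"))
  expect_equal(mos, matrix(as.numeric(sc$labels$labels), 64, 64))
  expect_error(tile_scene(pcac, fs, sc$labels, tile = 20), "multiple of 16")
})

test_that("non-divisible scenes are reflect-padded into full tiles", {
  withr::with_seed(1, {
    arr <- array(runif(80 * 70 * 6), c(80, 70, 6))
  })
  pcac <- spectral_cube(arr, wavelengths = 1:6)
  lab <- label_map(matrix(1L, 80, 70), class_scheme("a"))
  tiles <- tile_scene(pcac, NULL, lab, tile = 32)
  expect_length(tiles$tiles, ceiling(80 / 32) * ceiling(70 / 32))  # 3 x 3
  sizes <- vapply(tiles$tiles, function(t) dim(t$spectral)[1], numeric(1))
  expect_true(all(sizes == 32))
  # padded area is excluded from the valid extent
  last <- tiles$tiles[[9]]
  expect_identical(last$valid_h, 80L - 64L)
  expect_identical(last$valid_w, 70L - 64L)
  mos <- mosaic_tiles(tiles, lapply(tiles$tiles, function(t) t$spectral[, , 1]))
  expect_equal(mos, arr[, , 1])
  small <- label_map(matrix(1L, 20, 20), class_scheme("a"))
  cube_small <- spectral_cube(array(0.2, c(20, 20, 2)), 1:2)
  expect_warning(one <- tile_scene(cube_small, NULL, small, tile = 32),
                 "single padded tile")
  expect_length(one$tiles, 1)
})

test_that("the 8:2 split is seeded, disjoint and exhaustive", {
  sc <- tiny_scene(seed = 8, size = 64)
  pcac <- apply_pca(sc$cube, fit_pca(sc$cube, 6))
  tiles <- tile_scene(pcac, NULL, sc$labels, tile = 16)  # 16 tiles
  sp <- split_tiles(tiles, 0.8, seed = 4)
  expect_length(sp$train$tiles, 13)  # ceiling(0.8 * 16)
  expect_length(sp$test$tiles, 3)
  key <- function(t) paste(t$origin, collapse = ",")
  train_keys <- vapply(sp$train$tiles, key, character(1))
  test_keys <- vapply(sp$test$tiles, key, character(1))
  expect_length(intersect(train_keys, test_keys), 0)
  expect_setequal(c(train_keys, test_keys),
                  vapply(tiles$tiles, key, character(1)))
  sp2 <- split_tiles(tiles, 0.8, seed = 4)
  expect_identical(vapply(sp2$train$tiles, key, character(1)), train_keys)
})
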