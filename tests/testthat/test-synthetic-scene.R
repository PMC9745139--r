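# Synthetic labelled hyperspectral scenes.

test_that("endmembers respect kind contracts and the separation floor", {
  spec <- scene_spec(64, 64, n_bands = 32, n_classes = 5,
                     class_kinds = c("vegetation", "water", "bare", "built",
                                     "vegetation"),
                     seed = 7)
  ems <- generate_endmembers(spec)
  wl <- seq(400, 1000, length.out = 32)
  red <- wl >= 620 & wl <= 700
  nir <- wl >= 760 & wl <= 950
  expect_length(ems, 5)
  for (e in ems) {
    expect_true(all(e$spectrum >= 0 & e$spectrum <= 1))
    # smoothness: bounded first difference
    expect_lt(max(abs(diff(e$spectrum))), 0.15)
    if (e$kind == "vegetation")
      expect_gt(mean(e$spectrum[nir]), mean(e$spectrum[red]))
    if (e$kind == "water")
      expect_lt(mean(e$spectrum[nir]), mean(e$spectrum[red]))
  }
  # pairwise spectral angles all above the floor, recomputed directly
  for (i in 1:4) for (j in (i + 1):5) {
    a <- ems[[i]]$spectrum; b <- ems[[j]]$spectrum
    ang <- acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
    expect_gte(ang, 0.05)
  }
  # seeded determinism
  ems2 <- generate_endmembers(spec)
  expect_identical(ems, ems2)
})

test_that("an impossible separation request fails loudly", {
  spec <- scene_spec(32, 32, n_bands = 8, n_classes = 12,
                     class_kinds = "built", seed = 1)
  expect_error(generate_endmembers(spec, min_angle = 0.5), "separation floor")
})

test_that("class maps cover all classes with contiguous blobs", {
  spec <- scene_spec(64, 64, n_bands = 8, n_classes = 3, seed = 3)
  cm <- generate_class_map(spec)
  expect_setequal(unique(as.vector(cm$labels)), 1:3)
  expect_identical(cm$labels, generate_class_map(spec)$labels)

  # very smooth fields -> few large regions; count 4-connected components
  spec_big <- scene_spec(64, 64, n_bands = 8, n_classes = 3,
                         blob_smoothness = 48, seed = 3)
  lab <- generate_class_map(spec_big)$labels
  n_comp <- 0
  seen <- matrix(FALSE, nrow(lab), ncol(lab))
  for (r0 in seq_len(nrow(lab))) for (c0 in seq_len(ncol(lab))) {
    if (seen[r0, c0]) next
    n_comp <- n_comp + 1
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(lab) && q[2] >= 1 && q[2] <= ncol(lab) &&
            !seen[q[1], q[2]] && lab[q[1], q[2]] == lab[p[1], p[2]]) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
  }
  expect_lte(n_comp, 3 * 4)
})

test_that("rendering is exact for degenerate parameters and statistically faithful otherwise", {
  spec0 <- scene_spec(64, 64, n_bands = 16, n_classes = 3,
                      noise_sigma = 0, texture_amplitude = 0, seed = 9)
  ems <- generate_endmembers(spec0)
  cm <- generate_class_map(spec0)
  cube0 <- render_scene(spec0, ems, cm)
  for (ci in 1:3) {
    px <- which(cm$labels == ci)
    band_mat <- matrix(cube0$data, 64 * 64, 16)[px, , drop = FALSE]
    expect_equal(unname(band_mat[1, ]), ems[[ci]]$spectrum, tolerance = 1e-12)
    expect_lt(max(abs(sweep(band_mat, 2, ems[[ci]]$spectrum))), 1e-12)
  }

  spec <- scene_spec(64, 64, n_bands = 16, n_classes = 3, seed = 9)
  cube <- render_scene(spec, ems, cm)
  expect_true(all(cube$data >= 0 & cube$data <= 1))
  expect_identical(cube$data, render_scene(spec, ems, cm)$data)
  # per-class mean spectrum close to the endmember (texture is zero-mean)
  for (ci in 1:3) {
    px <- which(cm$labels == ci)
    mean_spec <- colMeans(matrix(cube$data, 64 * 64, 16)[px, , drop = FALSE])
    tol <- 3 * spec$noise_sigma / sqrt(length(px)) + spec$texture_amplitude * 0.5
    expect_lt(max(abs(mean_spec - ems[[ci]]$spectrum)), tol)
  }
})

test_that("adjacent bands of a rendered cube are strongly correlated at default spacing", {
  for (seed in c(21, 34)) {
    sc <- simulate_scene(scene_spec(96, 96, n_classes = 5, seed = seed))
    X <- matrix(sc$cube$data, 96 * 96, 32)
    cors <- vapply(1:31, function(b) cor(X[, b], X[, b + 1]), numeric(1))
    expect_true(all(cors >= 0.9))
  }
})

test_that("noise-free NDVI is positive on vegetation and negative on water", {
  spec <- scene_spec(64, 64, n_bands = 16, n_classes = 2,
                     class_kinds = c("vegetation", "water"),
                     noise_sigma = 0, texture_amplitude = 0, seed = 13)
  sc <- simulate_scene(spec)
  ndvi <- compute_ndvi(sc$cube)
  expect_true(all(ndvi[sc$labels$labels == 1] > 0))
  expect_true(all(ndvi[sc$labels$labels == 2] < 0))
})

test_that("the full scene is reproducible from one seed", {
  a <- tiny_scene(seed = 4)
  b <- tiny_scene(seed = 4)
  expect_identical(a$cube$data, b$cube$data)
  expect_identical(a$labels$labels, b$labels$labels)
  c <- tiny_scene(seed = 5)
  expect_false(identical(a$cube$data, c$cube$data))
})
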