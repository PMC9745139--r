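# PCA band reduction, tiling and train/test splitting.

#' Fit standardized PCA on a hyperspectral cube
#'
#' Pixels are flattened to a samples x bands matrix, standardized per band
#' (subtract mean, divide by standard deviation), and the covariance of the
#' standardized data (= the band correlation matrix) is eigendecomposed.
#' The top-`k` eigenvectors, ordered by eigenvalue, are the components; each
#' component's sign is fixed so its largest-magnitude loading is positive,
#' making the decomposition deterministic.
#'
#' @param cube a [spectral_cube()].
#' @param k number of components to keep (default 6, matching the six
#'   principal-component channels fed to the network).
#' @return An object of class `pca_model` with fields `mean`, `scale`
#'   (per-band), `components` (B x k, orthonormal columns), `eigenvalues`
#'   and `explained_variance_ratio`.
#' @details A constant band (zero variance) gets scale 1 with a warning
#'   rather than dividing by zero.
#' @examples
#' sc <- simulate_scene(scene_spec(64, 64, n_bands = 16, n_classes = 3, seed = 3))
#' m <- fit_pca(sc$cube, k = 6)
#' round(m$explained_variance_ratio, 3)
#' @export
fit_pca <- function(cube, k = 6) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$data)
  B <- d[3]
  if (!is_count(k, 1) || k > B) stopf("k must be in 1..%d", B)
  X <- matrix(cube$data, d[1] * d[2], B)
  if (nrow(X) < k + 1) stopf("need at least k + 1 pixels to fit %d components", k)
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  zero <- sdev == 0
  if (any(zero)) {
    warnf("%d constant band(s); their scale is set to 1", sum(zero))
    sdev[zero] <- 1
  }
  Z <- colscale(sweep(X, 2, mu, "-"), 1 / sdev)
  R <- crossprod(Z) / (nrow(Z) - 1)
  eig <- eigen(R, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  comp <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  structure(list(mean = mu, scale = sdev,
                 components = comp,
                 eigenvalues = vals[seq_len(k)],
                 explained_variance_ratio = vals[seq_len(k)] / sum(vals)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d bands -> %d components (%.1f%% variance)\n",
              nrow(x$components), ncol(x$components),
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Project a cube onto fitted principal components
#'
#' Standardizes with the model's per-band mean/scale and projects onto the
#' component loadings. The result is a [spectral_cube()] whose band axis
#' holds component scores; its "wavelengths" are the component indices.
#'
#' @param cube a [spectral_cube()] with the same band count the model was
#'   fitted on.
#' @param model a `pca_model` from [fit_pca()].
#' @return A [spectral_cube()] with `k` bands of PCA scores.
#' @export
apply_pca <- function(cube, model) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(model, "pca_model"))
  d <- dim(cube$data)
  if (d[3] != nrow(model$components))
    stopf("cube has %d bands but the model was fitted on %d",
          d[3], nrow(model$components))
  X <- matrix(cube$data, d[1] * d[2], d[3])
  Z <- colscale(sweep(X, 2, model$mean, "-"), 1 / model$scale)
  S <- Z %*% model$components
  spectral_cube(array(S, dim = c(d[1], d[2], ncol(S))),
                wavelengths = seq_len(ncol(S)))
}

## ---- tiling -----------------------------------------------------------

reflect_pad_matrix <- function(m, bottom, right) {
  if (bottom > 0) {
    src <- nrow(m) - seq_len(bottom)  # mirror, edge row excluded
    m <- rbind(m, m[src, , drop = FALSE])
  }
  if (right > 0) {
    src <- ncol(m) - seq_len(right)
    m <- cbind(m, m[, src, drop = FALSE])
  }
  m
}

reflect_pad_array <- function(a, bottom, right) {
  d <- dim(a)
  out <- array(0, dim = c(d[1] + bottom, d[2] + right, d[3]))
  for (b in seq_len(d[3])) out[, , b] <- reflect_pad_matrix(a[, , b], bottom, right)
  out
}

#' Cut a scene into non-overlapping square tiles
#'
#' The spectral (PCA) raster, the artificial-feature raster and the label
#' raster are cut on one common grid. Right/bottom remainders are padded by
#' reflection to full tile size; the padding extent is recorded per tile
#' (`valid_h`, `valid_w`) so that training masks and evaluation can ignore
#' padded pixels, and so mosaicking is an exact inverse.
#'
#' @param pca_cube a [spectral_cube()] of PCA scores (the spectral input).
#' @param feature_stack a [feature_stack()] (the artificial input), or `NULL`
#'   for single-input experiments.
#' @param labels a [label_map()].
#' @param tile tile edge in pixels; must be divisible by 16 (four 2x
#'   downsamplings). Default 64, the desk-scale stand-in for full-scene
#'   512-pixel tiles.
#' @return An object of class `tile_set`: list of tiles
#'   (`spectral`, `artificial`, `labels`, `origin`, `valid_h`, `valid_w`)
#'   plus the scene extent.
#' @export
tile_scene <- function(pca_cube, feature_stack, labels, tile = 64) {
  stopifnot(inherits(pca_cube, "spectral_cube"), inherits(labels, "label_map"))
  if (!is_count(tile, 16) || tile %% 16 != 0)
    stopf("tile size must be a positive multiple of 16, got %s", tile)
  d <- dim(pca_cube$data)
  H <- d[1]; W <- d[2]
  if (!identical(dim(labels$labels), c(H, W)))
    stopf("label raster size does not match the cube")
  art <- NULL
  if (!is.null(feature_stack)) {
    stopifnot(inherits(feature_stack, "feature_stack"))
    if (!identical(dim(feature_stack$data)[1:2], c(H, W)))
      stopf("feature stack size does not match the cube")
    art <- feature_stack$data
  }
  if (H < tile || W < tile)
    warnf("scene (%d x %d) smaller than one %d-pixel tile; emitting a single padded tile",
          H, W, tile)
  nr <- max(1L, as.integer(ceiling(H / tile)))
  nc <- max(1L, as.integer(ceiling(W / tile)))
  pad_b <- nr * tile - H
  pad_r <- nc * tile - W
  spec_p <- reflect_pad_array(pca_cube$data, pad_b, pad_r)
  art_p <- if (!is.null(art)) reflect_pad_array(art, pad_b, pad_r)
  lab_p <- reflect_pad_matrix(labels$labels, pad_b, pad_r)
  tiles <- vector("list", nr * nc)
  k <- 1L
  for (tc in seq_len(nc)) {
    for (tr in seq_len(nr)) {
      rows <- ((tr - 1L) * tile + 1L):(tr * tile)
      cols <- ((tc - 1L) * tile + 1L):(tc * tile)
      tiles[[k]] <- list(
        spectral = spec_p[rows, cols, , drop = FALSE],
        artificial = if (!is.null(art_p)) art_p[rows, cols, , drop = FALSE],
        labels = lab_p[rows, cols, drop = FALSE],
        origin = c(row = rows[1], col = cols[1]),
        valid_h = as.integer(min(tile, H - rows[1] + 1L)),
        valid_w = as.integer(min(tile, W - cols[1] + 1L)))
      k <- k + 1L
    }
  }
  structure(list(tiles = tiles, tile = as.integer(tile),
                 scene_dim = c(H, W), scheme = labels$scheme, role = "all"),
            class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("<tile_set> %d tiles of %d px (%s) from a %d x %d scene\n",
              length(x$tiles), x$tile, x$role, x$scene_dim[1], x$scene_dim[2]))
  invisible(x)
}

#' Split tiles into training and test sets
#'
#' Seeded shuffle; the first `ceiling(ratio * n)` tiles train, the rest
#' test. The split is at the tile level — the protocol tiles the scene
#' first, then divides tiles 8:2.
#'
#' @param tiles a `tile_set` from [tile_scene()].
#' @param ratio training fraction (default 0.8).
#' @param seed integer seed for the shuffle.
#' @return `list(train = tile_set, test = tile_set)`; disjoint, exhaustive.
#' @export
split_tiles <- function(tiles, ratio = 0.8, seed = 1L) {
  stopifnot(inherits(tiles, "tile_set"))
  n <- length(tiles$tiles)
  if (n < 2) stopf("need at least 2 tiles to split")
  perm <- with_seed(child_seed(seed, "split"), sample.int(n))
  n_train <- as.integer(ceiling(ratio * n))
  mk <- function(idx, role) {
    out <- tiles
    out$tiles <- tiles$tiles[idx]
    out$role <- role
    out
  }
  list(train = mk(perm[seq_len(n_train)], "train"),
       test = mk(perm[setdiff(seq_len(n), seq_len(n_train))], "test"))
}

#' Mosaic per-tile rasters back to scene extent
#'
#' Inverse of [tile_scene()] for any per-tile H x W matrix (e.g. predicted
#' labels): padding is stripped using the recorded valid extents and tiles
#' are placed at their origins.
#'
#' @param tiles a `tile_set`.
#' @param per_tile list of `tile x tile` matrices, one per tile.
#' @return An `H x W` matrix at the original scene extent (cells not covered
#'   by `tiles` are `NA`).
#' @export
mosaic_tiles <- function(tiles, per_tile) {
  stopifnot(inherits(tiles, "tile_set"), length(per_tile) == length(tiles$tiles))
  out <- matrix(NA, tiles$scene_dim[1], tiles$scene_dim[2])
  for (i in seq_along(tiles$tiles)) {
    t <- tiles$tiles[[i]]
    rows <- t$origin["row"]:(t$origin["row"] + t$valid_h - 1L)
    cols <- t$origin["col"]:(t$origin["col"] + t$valid_w - 1L)
    out[rows, cols] <- per_tile[[i]][seq_len(t$valid_h), seq_len(t$valid_w)]
  }
  out
}
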