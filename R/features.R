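# Hand-crafted feature branch: NDVI, GLCM texture maps, Sobel edges.

#' Normalized difference vegetation index
#'
#' `NDVI = (NIR - R) / (NIR + R)` per pixel, with the near-infrared and red
#' bands picked by nearest wavelength. Positive NDVI indicates vegetation
#' cover (the red edge makes NIR reflectance exceed red); negative indicates
#' water/snow/cloud; where `NIR + R == 0` the output is 0, the rock /
#' bare-soil convention. Being a ratio, NDVI is invariant to uniform scaling
#' of the cube.
#'
#' @param cube a [spectral_cube()] with wavelength metadata.
#' @param nir_nm,red_nm target wavelengths in nm (defaults 800 / 670).
#' @param tolerance_nm band-match tolerance passed to
#'   [select_band_by_wavelength()].
#' @return `H x W` matrix in `[-1, 1]`.
#' @examples
#' cube <- spectral_cube(array(c(0.2, 0.8), c(1, 1, 2)), c(670, 800))
#' compute_ndvi(cube)  # (0.8 - 0.2)/(0.8 + 0.2) = 0.6
#' @export
compute_ndvi <- function(cube, nir_nm = 800, red_nm = 670, tolerance_nm = 50) {
  i_nir <- select_band_by_wavelength(cube, nir_nm, tolerance_nm)
  i_red <- select_band_by_wavelength(cube, red_nm, tolerance_nm)
  nir <- cube$data[, , i_nir]
  red <- cube$data[, , i_red]
  denom <- nir + red
  out <- (nir - red) / denom
  out[denom == 0] <- 0
  out
}

#' Quantize a gray image to integer levels
#'
#' Min-max linear binning into `[0, levels)`; a constant image maps to
#' bin 0. Prerequisite for co-occurrence counting.
#'
#' @param image finite numeric matrix.
#' @param levels number of gray levels (default 16).
#' @return Integer matrix with values in `0..(levels - 1)`.
#' @export
quantize_gray <- function(image, levels = 16) {
  if (any(!is.finite(image))) stopf("image must be finite")
  rng <- range(image)
  if (rng[1] == rng[2]) {
    q <- matrix(0L, nrow(image), ncol(image))
  } else {
    q <- floor((image - rng[1]) / (rng[2] - rng[1]) * levels)
    q <- matrix(as.integer(pmin(q, levels - 1L)), nrow(image), ncol(image))
  }
  q
}

glcm_default_offsets <- function() {
  matrix(c(0L, 1L, 1L, 0L, 1L, 1L, 1L, -1L), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("dr", "dc")))
}

#' GLCM features of a single window
#'
#' Accumulates symmetric co-occurrence counts `P(i, j)` over every pixel
#' pair inside the window at the given offsets, normalizes them to sum 1,
#' and returns the four texture statistics used by the artificial branch:
#' \describe{
#'   \item{homogeneity}{`sum P / (1 + (i - j)^2)`}
#'   \item{mean}{`sum i * P_marginal(i)`}
#'   \item{dissimilarity}{`sum P * |i - j|`}
#'   \item{entropy}{`-sum P * log P` over `P > 0` (natural log)}
#' }
#'
#' @param window `w x w` integer matrix of quantized gray levels.
#' @param levels number of gray levels.
#' @param offsets integer matrix of `(dr, dc)` offsets; default the four
#'   symmetric directions (0,1), (1,0), (1,1), (1,-1).
#' @return Named numeric vector `(homogeneity, mean, dissimilarity, entropy)`.
#' @export
glcm_window_features <- function(window, levels = 16,
                                 offsets = glcm_default_offsets()) {
  if (!is.matrix(window) || nrow(window) < 1) stopf("window must be a matrix")
  if (nrow(offsets) < 1) stopf("offsets must be nonempty")
  w_h <- nrow(window); w_w <- ncol(window)
  P <- matrix(0, levels, levels)
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1]; dc <- offsets[k, 2]
    for (cc in seq_len(w_w)) {
      for (rr in seq_len(w_h)) {
        pr <- rr + dr; pc <- cc + dc
        if (pr < 1 || pr > w_h || pc < 1 || pc > w_w) next
        i <- window[rr, cc] + 1L; j <- window[pr, pc] + 1L
        P[i, j] <- P[i, j] + 1
        P[j, i] <- P[j, i] + 1
      }
    }
  }
  total <- sum(P)
  if (total == 0)
    stopf("window has no valid pixel pairs at the given offsets")
  P <- P / total
  lv <- 0:(levels - 1)
  D <- abs(outer(lv, lv, "-"))
  pos <- P > 0
  c(homogeneity = sum(P / (1 + D^2)),
    mean = sum(lv * rowSums(P)),
    dissimilarity = sum(P * D),
    entropy = -sum(P[pos] * log(P[pos])))
}

#' Sliding-window GLCM feature maps
#'
#' For every pixel, [glcm_window_features()] of the `window x window`
#' neighbourhood centred on it (reflect padding at the borders, so the
#' feature rasters stay aligned pixel-for-pixel with the image).
#'
#' @param image numeric matrix (will be quantized with [quantize_gray()]
#'   unless already integer in `[0, levels)`).
#' @param window odd window edge (default 3).
#' @param levels gray levels (default 16).
#' @param offsets as in [glcm_window_features()].
#' @return `H x W x 4` array, channels
#'   `[homogeneity, mean, dissimilarity, entropy]`.
#' @export
glcm_map <- function(image, window = 3, levels = 16,
                     offsets = glcm_default_offsets()) {
  if (window %% 2 != 1) stopf("window must be odd")
  if (is.integer(image) && all(image >= 0 & image < levels)) {
    q <- image
  } else {
    q <- quantize_gray(image, levels)
  }
  storage.mode(offsets) <- "integer"
  flat <- .glcm_map(q, as.integer(levels), as.integer(window), offsets)
  arr <- array(flat, dim = c(nrow(image), ncol(image), 4))
  dimnames(arr) <- list(NULL, NULL,
                        c("homogeneity", "mean", "dissimilarity", "entropy"))
  arr
}

#' Sobel edge magnitude
#'
#' Cross-correlates the image with the transverse and longitudinal 3x3
#' Sobel factors
#' \preformatted{
#'   gx: -1 0 1     gy: -1 -2 -1
#'       -2 0 2          0  0  0
#'       -1 0 1          1  2  1
#' }
#' (reflect padding) and returns `sqrt(gx^2 + gy^2)`.
#'
#' @param image finite numeric matrix.
#' @return `H x W` non-negative magnitude matrix.
#' @export
sobel_edges <- function(image) {
  if (any(!is.finite(image))) stopf("image must be finite")
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)        # column-major:
  ky <- t(kx)                                                 # kx[r,c], cols -1,0,1
  X <- matrix(image, length(image), 1)
  H <- nrow(image); W <- ncol(image)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  for (dr in -1:1) {
    for (dc in -1:1) {
      s <- matrix(.shift_gather(X, H, W, 1L, dr, dc), H, W)
      gx <- gx + kx[dr + 2, dc + 2] * s
      gy <- gy + ky[dr + 2, dc + 2] * s
    }
  }
  sqrt(gx^2 + gy^2)
}

#' Build the 6-channel artificial-feature input
#'
#' Stacks, in canonical order, `[ndvi, glcm_homogeneity, glcm_mean,
#' glcm_dissimilarity, glcm_entropy, sobel_magnitude]`. NDVI comes from the
#' raw reflectance cube; the GLCM maps and the Sobel magnitude are computed
#' on the first principal-component image (rescaled to `[0, 1]`), the
#' component that carries most of the spectral variance. Each channel is
#' then min-max normalized to `[0, 1]` with the affine map recorded.
#'
#' @param cube the raw [spectral_cube()] (with wavelengths).
#' @param pca_model optional `pca_model`; fitted on `cube` when `NULL`.
#' @param window,levels GLCM parameters (defaults 3 and 16).
#' @param nir_nm,red_nm NDVI band targets.
#' @return A `feature_stack` object: `data` (`H x W x 6`), `channel_names`,
#'   and `normalization` (per-channel `min`/`max` of the raw feature).
#' @export
build_artificial_stack <- function(cube, pca_model = NULL, window = 3,
                                   levels = 16, nir_nm = 800, red_nm = 670) {
  stopifnot(inherits(cube, "spectral_cube"))
  ndvi <- compute_ndvi(cube, nir_nm, red_nm)
  if (is.null(pca_model)) pca_model <- fit_pca(cube, k = 1)
  pc1 <- apply_pca(cube, pca_model)$data[, , 1]
  rng <- range(pc1)
  pc1 <- if (rng[1] == rng[2]) pc1 * 0 else (pc1 - rng[1]) / diff(rng)
  g <- glcm_map(pc1, window = window, levels = levels)
  sob <- sobel_edges(pc1)
  raw <- array(0, dim = c(nrow(ndvi), ncol(ndvi), 6))
  raw[, , 1] <- ndvi
  raw[, , 2:5] <- g
  raw[, , 6] <- sob
  feature_stack(raw)
}

#' Feature-stack container
#'
#' Normalizes each channel of a raw `H x W x 6` artificial-feature array to
#' `[0, 1]` (min-max), recording the affine map per channel.
#'
#' @param raw `H x W x 6` array in canonical channel order.
#' @return An object of class `feature_stack`.
#' @export
feature_stack <- function(raw) {
  if (!is.array(raw) || length(dim(raw)) != 3 || dim(raw)[3] != 6)
    stopf("expected an H x W x 6 array")
  if (any(!is.finite(raw))) stopf("feature channels must be finite")
  nm <- c("ndvi", "glcm_homogeneity", "glcm_mean", "glcm_dissimilarity",
          "glcm_entropy", "sobel_magnitude")
  norm <- data.frame(channel = nm, min = NA_real_, max = NA_real_)
  out <- raw
  for (ch in 1:6) {
    rng <- range(raw[, , ch])
    norm$min[ch] <- rng[1]; norm$max[ch] <- rng[2]
    out[, , ch] <- if (rng[1] == rng[2]) 0 else (raw[, , ch] - rng[1]) / diff(rng)
  }
  dimnames(out) <- list(NULL, NULL, nm)
  structure(list(data = out, channel_names = nm, normalization = norm,
                 raw_ndvi_range = range(raw[, , 1])),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<feature_stack> %d x %d x 6 [%s]\n", d[1], d[2],
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}
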