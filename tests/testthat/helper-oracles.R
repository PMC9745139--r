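# Independent brute-force oracles and small fixtures, built in code.

# Mirror (edge-excluded) reflection of an out-of-range index, 1-based.
ref_idx <- function(i, n) {
  if (n == 1) return(1L)
  while (i < 1 || i > n) {
    if (i < 1) i <- 2 - i
    if (i > n) i <- 2 * n - i
  }
  i
}

pad_reflect <- function(m, half) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H + 2 * half, W + 2 * half)
  for (r in seq_len(H + 2 * half))
    for (cc in seq_len(W + 2 * half))
      out[r, cc] <- m[ref_idx(r - half, H), ref_idx(cc - half, W)]
  out
}

# Naive pair-enumeration GLCM of one window: every in-window pixel, every
# offset, both directions, tallied one pair at a time.
glcm_oracle_window <- function(window, levels, offsets) {
  pairs_i <- integer(0); pairs_j <- integer(0)
  for (k in seq_len(nrow(offsets))) {
    for (cc in seq_len(ncol(window))) {
      for (rr in seq_len(nrow(window))) {
        pr <- rr + offsets[k, 1]; pc <- cc + offsets[k, 2]
        if (pr >= 1 && pr <= nrow(window) && pc >= 1 && pc <= ncol(window)) {
          pairs_i <- c(pairs_i, window[rr, cc], window[pr, pc])
          pairs_j <- c(pairs_j, window[pr, pc], window[rr, cc])
        }
      }
    }
  }
  P <- matrix(0, levels, levels)
  for (t in seq_along(pairs_i))
    P[pairs_i[t] + 1, pairs_j[t] + 1] <- P[pairs_i[t] + 1, pairs_j[t] + 1] + 1
  P <- P / sum(P)
  hom <- 0; mu <- 0; dis <- 0; ent <- 0
  for (i in 0:(levels - 1)) {
    for (j in 0:(levels - 1)) {
      p <- P[i + 1, j + 1]
      if (p > 0) {
        hom <- hom + p / (1 + (i - j)^2)
        dis <- dis + p * abs(i - j)
        ent <- ent - p * log(p)
        mu <- mu + i * p
      }
    }
  }
  c(homogeneity = hom, mean = mu, dissimilarity = dis, entropy = ent)
}

glcm_oracle_map <- function(image_q, window, levels, offsets) {
  half <- window %/% 2
  padded <- pad_reflect(image_q, half)
  out <- array(0, dim = c(nrow(image_q), ncol(image_q), 4))
  for (r in seq_len(nrow(image_q))) {
    for (cc in seq_len(ncol(image_q))) {
      win <- padded[r:(r + 2 * half), cc:(cc + 2 * half)]
      out[r, cc, ] <- glcm_oracle_window(win, levels, offsets)
    }
  }
  out
}

# Explicit double-loop cross-correlation with the two printed Sobel factors.
sobel_oracle <- function(image) {
  kx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  ky <- rbind(c(-1, -2, -1), c(0, 0, 0), c(1, 2, 1))
  p <- pad_reflect(image, 1)
  gx <- matrix(0, nrow(image), ncol(image)); gy <- gx
  for (r in seq_len(nrow(image))) {
    for (cc in seq_len(ncol(image))) {
      win <- p[r:(r + 2), cc:(cc + 2)]
      gx[r, cc] <- sum(kx * win)
      gy[r, cc] <- sum(ky * win)
    }
  }
  list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2))
}

# Element-wise BCE oracle: plain loops, no masking tricks.
bce_oracle <- function(p, y, mask = rep(TRUE, nrow(p))) {
  tot <- 0; n <- 0
  for (i in seq_len(nrow(p))) {
    if (!mask[i]) next
    for (j in seq_len(ncol(p))) {
      tot <- tot - (y[i, j] * log(p[i, j]) + (1 - y[i, j]) * log(1 - p[i, j]))
      n <- n + 1
    }
  }
  tot / n
}

# Naive per-pixel confusion counter.
confusion_oracle <- function(truth, pred, C) {
  cm <- matrix(0L, C, C)
  for (i in seq_along(truth)) {
    if (truth[i] == 0) next
    cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  }
  cm
}

# Small fixtures -----------------------------------------------------------

tiny_scene <- function(seed = 5, n_classes = 3, size = 64, bands = 16,
                       noise = 0.01) {
  simulate_scene(scene_spec(size, size, n_bands = bands, n_classes = n_classes,
                            noise_sigma = noise, seed = seed))
}

tiny_config <- function(branch_mode = "single", in_channels = 6, n_classes = 3,
                        ...) {
  net_config(channels = c(4, 6, 8, 10, 12), in_channels = in_channels,
             n_classes = n_classes, branch_mode = branch_mode, ...)
}

flip_lr <- function(a) {
  if (length(dim(a)) == 3) a[, rev(seq_len(dim(a)[2])), , drop = FALSE]
  else a[, rev(seq_len(ncol(a))), drop = FALSE]
}

# Mirror a model's spatial kernels left-right: kernel element (dr, dc) moves
# to (dr, -dc). Conv kernels are direction-sensitive, so flip equivariance
# of the network holds between a model and its kernel-mirrored twin; what
# the check exercises is the symmetry of every padding, pooling and
# upsampling stage.
flip_model_lr <- function(model) {
  perm <- integer(9)
  for (r in 1:9) {
    dr <- (r - 1) %/% 3 - 1
    dc <- (r - 1) %% 3 - 1
    perm[r] <- 3 * (dr + 1) + (-dc + 1) + 1
  }
  for (nm in names(model$params)) {
    if (grepl("_dw$", nm)) {
      model$params[[nm]] <- model$params[[nm]][perm, , drop = FALSE]
    } else if (grepl("_wc$", nm)) {
      w <- model$params[[nm]]
      cin <- nrow(w) / 9
      rows <- as.vector(vapply(perm, function(k) (k - 1) * cin + seq_len(cin),
                               numeric(cin)))
      model$params[[nm]] <- w[rows, , drop = FALSE]
    }
  }
  model
}
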