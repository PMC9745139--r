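# Differentiable tensor primitives.
#
# A "tensor" is list(x = (H*W*N) x C matrix, H, W, N): batch samples stacked
# along rows, column-major spatial layout within a sample, channels as
# matrix columns. Pointwise (1x1) convolutions are then plain matrix
# products (BLAS); depthwise convolution, pooling and upsampling run in
# compiled kernels. Every *_fwd returns what its *_bwd needs as a cache;
# backward passes are exact adjoints (verified by finite differences in the
# test-suite).

nn_tensor <- function(x, H, W, N) list(x = x, H = H, W = W, N = N)

# Stack a list of H x W x C arrays into one batch tensor.
batch_tensor <- function(arrs) {
  d <- dim(arrs[[1]])
  x <- do.call(rbind, lapply(arrs, function(a) matrix(a, d[1] * d[2], d[3])))
  nn_tensor(x, d[1], d[2], length(arrs))
}

# Split a batch tensor back into H x W x C arrays.
unbatch_tensor <- function(tn) {
  hw <- tn$H * tn$W
  lapply(seq_len(tn$N), function(n)
    array(tn$x[((n - 1) * hw + 1):(n * hw), , drop = FALSE],
          dim = c(tn$H, tn$W, ncol(tn$x))))
}

## ---- activations ------------------------------------------------------

#' h-swish activation
#'
#' `h_swish(x) = x * ReLU6(x + 3) / 6`, the piecewise-polynomial
#' approximation of swish used inside the feature-extraction module:
#' identity for `x >= 3`, zero for `x <= -3`, smooth in between.
#'
#' @param x numeric vector/matrix/array.
#' @return Same shape as `x`.
#' @examples
#' h_swish(c(-3, 0, 1, 3))  # 0, 0, 2/3, 3
#' @export
h_swish <- function(x) x * pmin(pmax(x + 3, 0), 6) / 6

h_swish_grad <- function(x) {
  ifelse(x >= 3, 1, ifelse(x <= -3, 0, (2 * x + 3) / 6))
}

relu_fwd <- function(x) pmax(x, 0)

## ---- pointwise (1x1) convolution --------------------------------------

pw_fwd <- function(X, W, b = NULL) {
  Y <- X %*% W
  if (!is.null(b)) Y <- Y + rep(b, each = nrow(Y))
  Y
}

pw_bwd <- function(G, X, W, has_bias = FALSE) {
  out <- list(dx = tcrossprod(G, W), dw = crossprod(X, G))
  if (has_bias) out$db <- colsums(G)
  out
}

## ---- batch normalization ----------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_fwd <- function(X, gamma, beta, training, rmean, rvar) {
  if (training) {
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu, "-")
    v <- colMeans(xc * xc)
    istd <- 1 / sqrt(v + BN_EPS)
    xhat <- colscale(xc, istd)
    new_rmean <- (1 - BN_MOMENTUM) * rmean + BN_MOMENTUM * mu
    new_rvar <- (1 - BN_MOMENTUM) * rvar + BN_MOMENTUM * v
    list(y = colscale(xhat, gamma) + rep(beta, each = nrow(X)),
         cache = list(xhat = xhat, istd = istd, gamma = gamma),
         rmean = new_rmean, rvar = new_rvar)
  } else {
    istd <- 1 / sqrt(rvar + BN_EPS)
    xhat <- colscale(sweep(X, 2, rmean, "-"), istd)
    list(y = colscale(xhat, gamma) + rep(beta, each = nrow(X)),
         cache = list(xhat = xhat, istd = istd, gamma = gamma),
         rmean = rmean, rvar = rvar)
  }
}

# Training-mode backward (batch statistics are part of the graph).
bn_bwd <- function(G, cache) {
  n <- nrow(G)
  dgamma <- colsums(G * cache$xhat)
  dbeta <- colsums(G)
  gg <- colscale(G, cache$gamma)  # d loss / d xhat
  dx <- colscale(gg - rep(colsums(gg) / n, each = n) -
                   cache$xhat * rep(colsums(gg * cache$xhat) / n, each = n),
                 cache$istd)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- spatial ops (compiled kernels) ------------------------------------

dw_fwd <- function(tn, Wdw) {
  nn_tensor(.dw_conv_fwd(tn$x, tn$H, tn$W, tn$N, Wdw), tn$H, tn$W, tn$N)
}

dw_bwd <- function(G, tn, Wdw) .dw_conv_bwd(G, tn$x, tn$H, tn$W, tn$N, Wdw)

pool_fwd <- function(tn) {
  r <- .maxpool2_fwd(tn$x, tn$H, tn$W, tn$N)
  list(tn = nn_tensor(r$y, tn$H %/% 2L, tn$W %/% 2L, tn$N), argmax = r$argmax)
}

pool_bwd <- function(G, argmax, H, W, N) .maxpool2_bwd(G, argmax, H, W, N)

up_fwd <- function(tn) {
  nn_tensor(.upsample2_fwd(tn$x, tn$H, tn$W, tn$N), 2L * tn$H, 2L * tn$W, tn$N)
}

up_bwd <- function(G, H, W, N) .upsample2_bwd(G, H, W, N)

# im2col for a 3x3 standard convolution: (H*W*N) x (9*C) with reflect padding.
im2col3 <- function(tn) {
  cols <- vector("list", 9)
  k <- 1
  for (dr in -1:1) for (dc in -1:1) {
    cols[[k]] <- .shift_gather(tn$x, tn$H, tn$W, tn$N, dr, dc)
    k <- k + 1
  }
  do.call(cbind, cols)
}

col2im3 <- function(dIM, H, W, N, C) {
  dX <- NULL
  k <- 1
  for (dr in -1:1) for (dc in -1:1) {
    slice <- dIM[, ((k - 1) * C + 1):(k * C), drop = FALSE]
    s <- .shift_scatter(slice, H, W, N, dr, dc)
    dX <- if (is.null(dX)) s else dX + s
    k <- k + 1
  }
  dX
}
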