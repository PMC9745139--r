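# Lightweight U-Net builders: residual depthwise-separable feature-extraction
# modules, single- and dual-branch topologies, and a plain-convolution
# baseline. Forward and backward passes are explicit (no autodiff framework);
# the backward pass mirrors the forward structure and is validated against
# finite differences in the test-suite.

#' Network architecture configuration
#'
#' @param levels encoder/decoder depth (default 5: four 2x poolings).
#' @param channels per-level widths, `length(channels) == levels`; default
#'   `c(32, 64, 128, 256, 512)`.
#' @param in_channels channels of the input(s): a single count for
#'   `branch_mode = "single"`, or a length-2 vector
#'   `(spectral, artificial)` for `"dual"` (default 6 per branch).
#' @param n_classes number of output classes (per-pixel logits).
#' @param residual add identity shortcuts inside feature-extraction modules
#'   whose input and output widths match (default `TRUE`). Identity-only:
#'   the toggle never changes the parameter count.
#' @param branch_mode `"single"` or `"dual"`.
#' @param block `"separable"` (depthwise-separable feature-extraction
#'   modules, h-swish) or `"plain"` (ordinary 3x3 convolutions + ReLU, the
#'   baseline U-Net).
#' @param upsample_mode `"bilinear"` (default) or `"nearest"`; either way a
#'   pointwise convolution halves the channel width after upsampling.
#' @return An object of class `net_config`.
#' @export
net_config <- function(levels = 5, channels = c(32, 64, 128, 256, 512),
                       in_channels = 6, n_classes = 2, residual = TRUE,
                       branch_mode = c("single", "dual"),
                       block = c("separable", "plain"),
                       upsample_mode = c("bilinear", "nearest")) {
  branch_mode <- match.arg(branch_mode)
  block <- match.arg(block)
  upsample_mode <- match.arg(upsample_mode)
  if (length(channels) != levels)
    stopf("`channels` must list one width per level (%d)", levels)
  if (branch_mode == "dual") {
    if (length(in_channels) == 1) in_channels <- rep(in_channels, 2)
    if (length(in_channels) != 2)
      stopf("dual-branch config needs in_channels of length 1 or 2")
  } else if (length(in_channels) != 1) {
    stopf("single-branch config needs a single in_channels")
  }
  structure(list(levels = as.integer(levels), modules_per_level = 2L,
                 channels = as.integer(channels),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes), residual = isTRUE(residual),
                 branch_mode = branch_mode, block = block,
                 upsample_mode = upsample_mode),
            class = "net_config")
}

#' Specification of one feature-extraction module
#'
#' The module is a 3x3 depthwise convolution, a 1x1 pointwise convolution,
#' batch normalization, an identity residual shortcut (only when
#' `in_channels == out_channels`), and an h-swish activation. Its parameter
#' count, `9 * C_in + C_in * C_out + 2 * C_out`, does not depend on the
#' residual toggle: identity shortcuts are parameter-free.
#'
#' @param in_channels,out_channels channel widths.
#' @param residual request a shortcut; it is used only if the widths match
#'   (`uses_residual` in the result), otherwise silently omitted per the
#'   identity-only rule.
#' @return An object of class `module_spec` with fields `in_channels`,
#'   `out_channels`, `uses_residual`, `param_count`.
#' @examples
#' module_spec(32, 32)$param_count  # 9*32 + 32*32 + 2*32 = 1376
#' @export
module_spec <- function(in_channels, out_channels, residual = TRUE) {
  ci <- as.integer(in_channels); co <- as.integer(out_channels)
  structure(list(in_channels = ci, out_channels = co,
                 uses_residual = isTRUE(residual) && ci == co,
                 param_count = 9L * ci + ci * co + 2L * co),
            class = "module_spec")
}

fem_param_names <- c("dw", "pw", "gamma", "beta")

he_dw <- function(c_in) matrix(rnorm(9 * c_in, 0, sqrt(2 / 9)), 9, c_in)
he_pw <- function(c_in, c_out) matrix(rnorm(c_in * c_out, 0, sqrt(2 / c_in)),
                                      c_in, c_out)
he_conv3 <- function(c_in, c_out)
  matrix(rnorm(9 * c_in * c_out, 0, sqrt(2 / (9 * c_in))), 9 * c_in, c_out)

#' Parameters for a standalone feature-extraction module
#'
#' @param spec a [module_spec()].
#' @param init `"he"` (Kaiming-normal) or `"zero"` (all convolution weights
#'   zero — useful for checking the identity shortcut).
#' @param seed RNG seed for `"he"` init.
#' @return Named list `dw` (9 x C_in), `pw` (C_in x C_out), `gamma`, `beta`.
#' @export
fem_params <- function(spec, init = c("he", "zero"), seed = 1L) {
  init <- match.arg(init)
  with_seed(seed, {
    if (init == "zero") {
      list(dw = matrix(0, 9, spec$in_channels),
           pw = matrix(0, spec$in_channels, spec$out_channels),
           gamma = rep(1, spec$out_channels), beta = rep(0, spec$out_channels))
    } else {
      list(dw = he_dw(spec$in_channels),
           pw = he_pw(spec$in_channels, spec$out_channels),
           gamma = rep(1, spec$out_channels), beta = rep(0, spec$out_channels))
    }
  })
}

#' Apply one feature-extraction module to an image tensor
#'
#' Order of operations: depthwise 3x3 (reflect "same" padding) -> pointwise
#' 1x1 -> batch norm -> identity shortcut added (when `uses_residual`) ->
#' h-swish. Spatial size is preserved.
#'
#' @param input `H x W x C_in` array.
#' @param spec a [module_spec()].
#' @param params from [fem_params()].
#' @param bn_identity bypass batch normalization (identity mode); used to
#'   probe the data path in isolation.
#' @return `H x W x C_out` array.
#' @export
feature_extraction_module <- function(input, spec, params = fem_params(spec),
                                      bn_identity = FALSE) {
  stopifnot(is.array(input), length(dim(input)) == 3)
  d <- dim(input)
  if (d[3] != spec$in_channels)
    stopf("input has %d channels, module expects %d", d[3], spec$in_channels)
  tn <- nn_tensor(matrix(input, d[1] * d[2], d[3]), d[1], d[2], 1L)
  D <- dw_fwd(tn, params$dw)
  P <- pw_fwd(D$x, params$pw)
  B <- if (bn_identity) P
       else bn_fwd(P, params$gamma, params$beta, training = FALSE,
                   rmean = rep(0, spec$out_channels),
                   rvar = rep(1 - BN_EPS, spec$out_channels))$y
  Z <- if (spec$uses_residual) B + tn$x else B
  array(h_swish(Z), dim = c(d[1], d[2], spec$out_channels))
}

## ---- model construction ------------------------------------------------

new_bn_state <- function(state, prefix, c_out) {
  state[[paste0(prefix, "_rmean")]] <- rep(0, c_out)
  state[[paste0(prefix, "_rvar")]] <- rep(1, c_out)
  state
}

add_block_params <- function(params, state, prefix, c_in, c_out, block) {
  if (block == "separable") {
    params[[paste0(prefix, "_dw")]] <- he_dw(c_in)
    params[[paste0(prefix, "_pw")]] <- he_pw(c_in, c_out)
  } else {
    params[[paste0(prefix, "_wc")]] <- he_conv3(c_in, c_out)
  }
  params[[paste0(prefix, "_gamma")]] <- rep(1, c_out)
  params[[paste0(prefix, "_beta")]] <- rep(0, c_out)
  list(params = params, state = new_bn_state(state, prefix, c_out))
}

encoder_widths <- function(config, branch) {
  c_in <- if (config$branch_mode == "dual") config$in_channels[branch]
          else config$in_channels
  c(c_in, config$channels)
}

#' Build a segmentation network
#'
#' `build_single_branch()` assembles the improved U-Net: a 5-level encoder
#' (two feature-extraction modules per level, 2x2 max pooling between
#' levels), a mirrored decoder (2x upsampling + pointwise reduction, skip
#' concatenation, two modules), and a final 1x1 convolution producing
#' per-pixel class logits. `build_dual_branch()` adds a second, structurally
#' identical encoder with independent weights; at every level the two
#' branches' pre-pool feature maps are concatenated and reduced back to the
#' level width by a pointwise convolution, forming the skip tensors and the
#' bottleneck of a single shared decoder.
#'
#' @param config a [net_config()] with the matching `branch_mode`.
#' @param seed RNG seed for He-normal weight initialization.
#' @return An object of class `hsiseg_model`.
#' @export
build_single_branch <- function(config, seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  if (config$branch_mode != "single")
    stopf("config$branch_mode must be 'single'")
  build_model_impl(config, seed)
}

#' @rdname build_single_branch
#' @export
build_dual_branch <- function(config, seed = 1L) {
  stopifnot(inherits(config, "net_config"))
  if (config$branch_mode != "dual")
    stopf("config$branch_mode must be 'dual'")
  build_model_impl(config, seed)
}

build_model_impl <- function(config, seed) {
  L <- config$levels
  ch <- config$channels
  params <- list(); state <- list()
  notes <- character()
  branches <- if (config$branch_mode == "dual") c("encA", "encB") else "enc"
  with_seed(child_seed(seed, "init"), {
    for (bi in seq_along(branches)) {
      widths <- encoder_widths(config, bi)
      for (l in seq_len(L)) {
        p1 <- sprintf("%s%d_m1", branches[bi], l)
        p2 <- sprintf("%s%d_m2", branches[bi], l)
        r <- add_block_params(params, state, p1, widths[l], ch[l], config$block)
        r <- add_block_params(r$params, r$state, p2, ch[l], ch[l], config$block)
        params <- r$params; state <- r$state
        if (config$residual && widths[l] != ch[l])
          notes <- unique(c(notes, sprintf(
            "module %s: shortcut omitted (channels %d -> %d, identity-only rule)",
            p1, widths[l], ch[l])))
      }
    }
    if (config$branch_mode == "dual") {
      for (l in seq_len(L)) {
        params[[sprintf("fuse%d_pw", l)]] <- he_pw(2 * ch[l], ch[l])
        params[[sprintf("fuse%d_b", l)]] <- rep(0, ch[l])
      }
    }
    for (l in rev(seq_len(L - 1))) {
      params[[sprintf("up%d_pw", l)]] <- he_pw(ch[l + 1], ch[l])
      params[[sprintf("up%d_b", l)]] <- rep(0, ch[l])
      r <- add_block_params(params, state, sprintf("dec%d_m1", l),
                            2 * ch[l], ch[l], config$block)
      r <- add_block_params(r$params, r$state, sprintf("dec%d_m2", l),
                            ch[l], ch[l], config$block)
      params <- r$params; state <- r$state
    }
    params$head_w <- he_pw(ch[1], config$n_classes)
    params$head_b <- rep(0, config$n_classes)
  })
  structure(list(config = config, params = params, state = state,
                 notes = notes, seed = as.integer(seed)),
            class = "hsiseg_model")
}

#' @export
print.hsiseg_model <- function(x, ...) {
  cat(sprintf("<hsiseg_model> %s-branch %s U-Net, %d levels [%s], %d classes, %s parameters\n",
              x$config$branch_mode,
              if (x$config$block == "separable") "depthwise-separable" else "plain",
              x$config$levels, paste(x$config$channels, collapse = ", "),
              x$config$n_classes,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Total scalar count over all weights, batch-norm scales/shifts and biases.
#' Identity residual shortcuts contribute nothing, so toggling `residual`
#' never changes this number.
#'
#' @param model an `hsiseg_model`.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "hsiseg_model"))
  sum(vapply(model$params, length, integer(1)))
}

## ---- forward / backward ------------------------------------------------

block_fwd <- function(prefix, tn, params, state, training, use_res, block) {
  gamma <- params[[paste0(prefix, "_gamma")]]
  beta <- params[[paste0(prefix, "_beta")]]
  rm_key <- paste0(prefix, "_rmean"); rv_key <- paste0(prefix, "_rvar")
  if (block == "separable") {
    D <- dw_fwd(tn, params[[paste0(prefix, "_dw")]])
    P <- pw_fwd(D$x, params[[paste0(prefix, "_pw")]])
  } else {
    IM <- im2col3(tn)
    P <- IM %*% params[[paste0(prefix, "_wc")]]
  }
  bnr <- bn_fwd(P, gamma, beta, training, state[[rm_key]], state[[rv_key]])
  state[[rm_key]] <- bnr$rmean; state[[rv_key]] <- bnr$rvar
  Z <- if (use_res) bnr$y + tn$x else bnr$y
  Y <- if (block == "separable") h_swish(Z) else relu_fwd(Z)
  cache <- list(prefix = prefix, tn = tn, bn = bnr$cache, Z = Z,
                use_res = use_res, block = block)
  if (block == "separable") cache$D <- D else cache$IM <- IM
  list(out = nn_tensor(Y, tn$H, tn$W, tn$N), cache = cache, state = state)
}

block_bwd <- function(G, cache, params, grads) {
  pre <- cache$prefix
  dZ <- if (cache$block == "separable") G * h_swish_grad(cache$Z)
        else G * (cache$Z > 0)
  bnb <- bn_bwd(dZ, cache$bn)
  grads[[paste0(pre, "_gamma")]] <- grads_add(grads[[paste0(pre, "_gamma")]], bnb$dgamma)
  grads[[paste0(pre, "_beta")]] <- grads_add(grads[[paste0(pre, "_beta")]], bnb$dbeta)
  if (cache$block == "separable") {
    Wpw <- params[[paste0(pre, "_pw")]]
    dD <- tcrossprod(bnb$dx, Wpw)
    grads[[paste0(pre, "_pw")]] <- grads_add(grads[[paste0(pre, "_pw")]],
                                             crossprod(cache$D$x, bnb$dx))
    r <- dw_bwd(dD, cache$tn, params[[paste0(pre, "_dw")]])
    grads[[paste0(pre, "_dw")]] <- grads_add(grads[[paste0(pre, "_dw")]], r$dw)
    dX <- r$dx
  } else {
    Wc <- params[[paste0(pre, "_wc")]]
    grads[[paste0(pre, "_wc")]] <- grads_add(grads[[paste0(pre, "_wc")]],
                                             crossprod(cache$IM, bnb$dx))
    dIM <- tcrossprod(bnb$dx, Wc)
    dX <- col2im3(dIM, cache$tn$H, cache$tn$W, cache$tn$N, ncol(cache$tn$x))
  }
  if (cache$use_res) dX <- dX + dZ
  list(dx = dX, grads = grads)
}

grads_add <- function(a, b) if (is.null(a)) b else a + b

nearest_idx <- function(H, W, N) {
  # output row -> input row for 2x nearest upsampling, 0-based
  o_row <- rep(0:(2 * H - 1), times = 2 * W)
  o_col <- rep(0:(2 * W - 1), each = 2 * H)
  per <- (o_col %/% 2) * H + (o_row %/% 2)
  as.vector(outer(per, (0:(N - 1)) * H * W, "+"))
}

upsample_fwd <- function(tn, mode) {
  if (mode == "bilinear") return(up_fwd(tn))
  idx <- nearest_idx(tn$H, tn$W, tn$N)
  nn_tensor(tn$x[idx + 1L, , drop = FALSE], 2L * tn$H, 2L * tn$W, tn$N)
}

upsample_bwd <- function(G, H, W, N, mode) {
  if (mode == "bilinear") return(up_bwd(G, H, W, N))
  idx <- nearest_idx(H, W, N)
  rowsum(G, group = idx, reorder = TRUE)
}

encoder_fwd <- function(branch, tn, model, training, state) {
  config <- model$config
  L <- config$levels
  widths <- encoder_widths(config, if (branch == "encB") 2L else 1L)
  feats <- vector("list", L)
  caches <- vector("list", L)
  for (l in seq_len(L)) {
    res1 <- config$residual && widths[l] == config$channels[l]
    b1 <- block_fwd(sprintf("%s%d_m1", branch, l), tn, model$params, state,
                    training, res1, config$block)
    state <- b1$state
    b2 <- block_fwd(sprintf("%s%d_m2", branch, l), b1$out, model$params, state,
                    training, config$residual, config$block)
    state <- b2$state
    feats[[l]] <- b2$out
    pool <- NULL
    if (l < L) {
      pr <- pool_fwd(b2$out)
      tn <- pr$tn
      pool <- list(argmax = pr$argmax, H = b2$out$H, W = b2$out$W, N = b2$out$N)
    }
    caches[[l]] <- list(m1 = b1$cache, m2 = b2$cache, pool = pool)
  }
  list(feats = feats, caches = caches, state = state)
}

# Backward through one encoder given per-level gradients w.r.t. its pre-pool
# feature maps (level L gradient is w.r.t. the bottleneck feature).
encoder_bwd <- function(branch, enc, dfeats, model, grads) {
  L <- model$config$levels
  dnext <- NULL  # gradient flowing into the pooled output of level l
  for (l in rev(seq_len(L))) {
    cc <- enc$caches[[l]]
    G <- dfeats[[l]]
    if (!is.null(dnext)) {
      p <- cc$pool
      G <- G + pool_bwd(dnext, p$argmax, p$H, p$W, p$N)
    }
    r2 <- block_bwd(G, cc$m2, model$params, grads)
    grads <- r2$grads
    r1 <- block_bwd(r2$dx, cc$m1, model$params, grads)
    grads <- r1$grads
    dnext <- if (l > 1) r1$dx else NULL
    if (l == 1) dinput <- r1$dx
  }
  list(grads = grads, dinput = dinput)
}

net_fwd <- function(model, tnS, tnA = NULL, training = FALSE) {
  config <- model$config
  L <- config$levels
  down <- 2^(L - 1)
  if (tnS$H %% down != 0 || tnS$W %% down != 0)
    stopf("input spatial size %d x %d is not divisible by %d",
          tnS$H, tnS$W, down)
  state <- model$state
  fw <- list()
  if (config$branch_mode == "dual") {
    if (is.null(tnA)) stopf("dual-branch model needs both inputs")
    if (tnA$H != tnS$H || tnA$W != tnS$W || tnA$N != tnS$N)
      stopf("the two branch inputs disagree in spatial size")
    encA <- encoder_fwd("encA", tnS, model, training, state)
    state <- encA$state
    encB <- encoder_fwd("encB", tnA, model, training, state)
    state <- encB$state
    fw$encA <- encA; fw$encB <- encB
    skips <- vector("list", L)
    fw$fuse <- vector("list", L)
    for (l in seq_len(L)) {
      Xcat <- cbind(encA$feats[[l]]$x, encB$feats[[l]]$x)
      W <- model$params[[sprintf("fuse%d_pw", l)]]
      Y <- pw_fwd(Xcat, W, model$params[[sprintf("fuse%d_b", l)]])
      skips[[l]] <- nn_tensor(Y, encA$feats[[l]]$H, encA$feats[[l]]$W,
                              encA$feats[[l]]$N)
      fw$fuse[[l]] <- list(Xcat = Xcat, l = l)
    }
    bottom <- skips[[L]]
  } else {
    enc <- encoder_fwd("enc", tnS, model, training, state)
    state <- enc$state
    fw$enc <- enc
    skips <- enc$feats
    bottom <- skips[[L]]
  }
  fw$dec <- vector("list", L - 1)
  for (l in rev(seq_len(L - 1))) {
    upin <- bottom
    up <- upsample_fwd(upin, config$upsample_mode)
    Wup <- model$params[[sprintf("up%d_pw", l)]]
    U <- pw_fwd(up$x, Wup, model$params[[sprintf("up%d_b", l)]])
    Xcat <- cbind(skips[[l]]$x, U)
    tn_cat <- nn_tensor(Xcat, up$H, up$W, up$N)
    b1 <- block_fwd(sprintf("dec%d_m1", l), tn_cat, model$params, state,
                    training, use_res = FALSE, config$block)
    state <- b1$state
    b2 <- block_fwd(sprintf("dec%d_m2", l), b1$out, model$params, state,
                    training, config$residual, config$block)
    state <- b2$state
    fw$dec[[l]] <- list(upin_dims = upin[c("H", "W", "N")], up = up,
                        skip_w = ncol(skips[[l]]$x), m1 = b1$cache,
                        m2 = b2$cache, l = l)
    bottom <- b2$out
  }
  logits <- pw_fwd(bottom$x, model$params$head_w, model$params$head_b)
  fw$head <- list(X = bottom$x)
  fw$logits <- nn_tensor(logits, bottom$H, bottom$W, bottom$N)
  fw$state <- state
  fw
}

net_bwd <- function(model, fw, dlogits) {
  config <- model$config
  L <- config$levels
  grads <- list()
  hb <- pw_bwd(dlogits, fw$head$X, model$params$head_w, has_bias = TRUE)
  grads$head_w <- hb$dw; grads$head_b <- hb$db
  G <- hb$dx
  dskips <- vector("list", L)
  for (l in seq_len(L - 1)) {
    dc <- fw$dec[[l]]
    r2 <- block_bwd(G, dc$m2, model$params, grads)
    grads <- r2$grads
    r1 <- block_bwd(r2$dx, dc$m1, model$params, grads)
    grads <- r1$grads
    sw <- dc$skip_w
    dskips[[l]] <- r1$dx[, seq_len(sw), drop = FALSE]
    dU <- r1$dx[, (sw + 1):ncol(r1$dx), drop = FALSE]
    ub <- pw_bwd(dU, dc$up$x, model$params[[sprintf("up%d_pw", l)]],
                 has_bias = TRUE)
    grads[[sprintf("up%d_pw", l)]] <- ub$dw
    grads[[sprintf("up%d_b", l)]] <- ub$db
    G <- upsample_bwd(ub$dx, dc$upin_dims$H, dc$upin_dims$W, dc$upin_dims$N,
                      config$upsample_mode)
  }
  dskips[[L]] <- G  # gradient w.r.t. the bottleneck feature
  if (config$branch_mode == "dual") {
    dA <- vector("list", L); dB <- vector("list", L)
    for (l in seq_len(L)) {
      fl <- fw$fuse[[l]]
      fb <- pw_bwd(dskips[[l]], fl$Xcat, model$params[[sprintf("fuse%d_pw", l)]],
                   has_bias = TRUE)
      grads[[sprintf("fuse%d_pw", l)]] <- fb$dw
      grads[[sprintf("fuse%d_b", l)]] <- fb$db
      cA <- ncol(fw$encA$feats[[l]]$x)
      dA[[l]] <- fb$dx[, seq_len(cA), drop = FALSE]
      dB[[l]] <- fb$dx[, (cA + 1):ncol(fb$dx), drop = FALSE]
    }
    rA <- encoder_bwd("encA", fw$encA, dA, model, grads)
    rB <- encoder_bwd("encB", fw$encB, dB, model, rA$grads)
    grads <- rB$grads
  } else {
    r <- encoder_bwd("enc", fw$enc, dskips, model, grads)
    grads <- r$grads
  }
  grads
}

#' Run a forward pass (inference mode)
#'
#' Evaluates the network with its running batch-norm statistics (no
#' stochastic components: deterministic given fixed weights).
#'
#' @param model an `hsiseg_model`.
#' @param spectral `H x W x C` array (or list of arrays) for the spectral
#'   branch; spatial dims must be divisible by `2^(levels - 1)`.
#' @param artificial second-branch input, required for dual-branch models.
#' @return `H x W x n_classes` logits array (list of arrays for list input).
#' @export
net_forward <- function(model, spectral, artificial = NULL) {
  stopifnot(inherits(model, "hsiseg_model"))
  listed <- is.list(spectral)
  specs <- if (listed) spectral else list(spectral)
  arts <- if (is.null(artificial)) NULL
          else if (is.list(artificial)) artificial else list(artificial)
  tnS <- batch_tensor(specs)
  tnA <- if (!is.null(arts)) batch_tensor(arts)
  fw <- net_fwd(model, tnS, tnA, training = FALSE)
  out <- unbatch_tensor(fw$logits)
  if (listed) out else out[[1]]
}
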