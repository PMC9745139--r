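# Per-class binary cross-entropy training with Adam.
#
# Each pixel-class decision is treated as an independent binary problem:
# logits pass through a sigmoid per class, the loss is the masked mean of
# -[y log p + (1-y) log(1-p)] over valid pixels and classes, and prediction
# fuses the per-class probabilities by argmax. Unlabeled pixels (id 0) and
# reflection-padded tile margins are excluded through the mask.

#' Training protocol configuration
#'
#' Defaults follow the full-scale protocol (batch 4, initial learning rate
#' 1e-4, up to 600 epochs) with a desk-scale epoch default of 30; the
#' epoch-100 step decay is off by default (constant schedule) and available
#' behind `lr_schedule = "step"`.
#'
#' @param batch_size tiles per batch (default 4).
#' @param max_epochs epochs to run (default 30; full-scale protocol: 600).
#' @param lr initial Adam learning rate (default 1e-4).
#' @param lr_schedule `"constant"` or `"step"` (multiply by `step_factor`
#'   at `step_epoch`).
#' @param step_epoch,step_factor step-schedule parameters (100, 0.1).
#' @param seed RNG seed controlling shuffling (and nothing else).
#' @param loss `"bce"` (per-class sigmoid, default) or `"softmax"`
#'   (multinomial cross-entropy alternative).
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 4, max_epochs = 30, lr = 1e-4,
                         lr_schedule = c("constant", "step"),
                         step_epoch = 100, step_factor = 0.1, seed = 1L,
                         loss = c("bce", "softmax")) {
  lr_schedule <- match.arg(lr_schedule)
  loss <- match.arg(loss)
  if (lr <= 0) stopf("lr must be positive")
  if (!is_count(batch_size, 1)) stopf("batch_size must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr = lr,
                 lr_schedule = lr_schedule, step_epoch = step_epoch,
                 step_factor = step_factor, seed = as.integer(seed),
                 loss = loss),
            class = "train_config")
}

#' One-hot encode a label raster
#'
#' Class id `k` lights plane `k`; id 0 (unlabeled) produces an all-zero row
#' and a `FALSE` mask entry, excluding the pixel from loss and metrics.
#'
#' @param labels integer matrix (or [label_map()]).
#' @param n_classes number of planes.
#' @return `list(y = pixels x n_classes binary matrix (column-major pixel
#'   order), mask = logical vector of valid pixels)`.
#' @export
one_hot_encode <- function(labels, n_classes) {
  lab <- if (inherits(labels, "label_map")) labels$labels else labels
  v <- as.integer(lab)
  y <- matrix(0, length(v), n_classes)
  pos <- which(v > 0)
  y[cbind(pos, v[pos])] <- 1
  list(y = y, mask = v > 0)
}

#' Per-class binary cross-entropy loss
#'
#' Masked mean over valid pixels and classes of
#' `-[y log p + (1 - y) log(1 - p)]`.
#'
#' @param predicted per-class probabilities in `(0, 1)`; matrix
#'   (pixels x classes) or array.
#' @param target one-hot targets of the same shape.
#' @param mask logical vector of valid pixels (rows); default all valid.
#' @return Scalar loss.
#' @examples
#' bce_loss(matrix(0.5), matrix(1))  # log(2)
#' @export
bce_loss <- function(predicted, target, mask = NULL) {
  p <- as.matrix(predicted); y <- as.matrix(target)
  if (!identical(dim(p), dim(y))) stopf("prediction/target shapes differ")
  if (is.null(mask)) mask <- rep(TRUE, nrow(p))
  if (!any(mask)) stopf("empty mask: no valid pixels to score")
  p <- p[mask, , drop = FALSE]; y <- y[mask, , drop = FALSE]
  -mean(y * log(p) + (1 - y) * log1p(-p))
}

# Numerically stable BCE from logits plus its gradient; mean over valid
# pixels and classes. Returns loss and d loss / d logits (zero on masked
# rows).
bce_from_logits <- function(z, y, mask) {
  if (!any(mask)) stopf("empty mask: no valid pixels to score")
  denom <- sum(mask) * ncol(z)
  zm <- z[mask, , drop = FALSE]; ym <- y[mask, , drop = FALSE]
  loss <- sum(pmax(zm, 0) - zm * ym + log1p(exp(-abs(zm)))) / denom
  g <- matrix(0, nrow(z), ncol(z))
  g[mask, ] <- (1 / (1 + exp(-zm)) - ym) / denom
  list(loss = loss, grad = g)
}

softmax_from_logits <- function(z, y, mask) {
  if (!any(mask)) stopf("empty mask: no valid pixels to score")
  denom <- sum(mask)
  zm <- z[mask, , drop = FALSE]
  zs <- zm - apply(zm, 1, max)
  ez <- exp(zs)
  p <- ez / rowSums(ez)
  ym <- y[mask, , drop = FALSE]
  loss <- -sum(ym * (zs - log(rowSums(ez)))) / denom
  g <- matrix(0, nrow(z), ncol(z))
  g[mask, ] <- (p - ym) / denom
  list(loss = loss, grad = g)
}

## ---- Adam --------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

## ---- tile batching -----------------------------------------------------

tile_mask <- function(t, tile) {
  m <- matrix(FALSE, tile, tile)
  m[seq_len(t$valid_h), seq_len(t$valid_w)] <- TRUE
  m
}

# Assemble a batch of tiles into network inputs and targets.
make_batch <- function(tiles, idx, n_classes, dual, tile) {
  ts <- tiles$tiles[idx]
  tnS <- batch_tensor(lapply(ts, `[[`, "spectral"))
  tnA <- if (dual) batch_tensor(lapply(ts, `[[`, "artificial"))
  y <- do.call(rbind, lapply(ts, function(t) one_hot_encode(t$labels, n_classes)$y))
  mask <- unlist(lapply(ts, function(t)
    as.vector(t$labels > 0 & tile_mask(t, tile))))
  list(tnS = tnS, tnA = tnA, y = y, mask = mask,
       labels = unlist(lapply(ts, function(t) as.vector(t$labels))))
}

## ---- training loop -----------------------------------------------------

#' Train a segmentation model
#'
#' Seeded shuffling each epoch, Adam updates at the configured learning
#' rate, per-epoch loss/accuracy history, and retention of the weights with
#' the best validation loss (evaluated on `validation` tiles when given).
#' Training aborts with the offending epoch reported if the loss becomes
#' non-finite.
#'
#' @param model an `hsiseg_model` from [build_single_branch()] /
#'   [build_dual_branch()].
#' @param train a `tile_set` of training tiles.
#' @param config a [train_config()].
#' @param validation optional `tile_set` scored (inference mode) after each
#'   epoch.
#' @param verbose print per-epoch progress.
#' @return An object of class `hsiseg_fit`: `model` (best-validation
#'   weights, or final weights without validation), `final_model`, and
#'   `history` (tibble: epoch, loss, accuracy, lr, val_loss, val_accuracy).
#' @export
train_model <- function(model, train, config = train_config(),
                        validation = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "hsiseg_model"), inherits(train, "tile_set"))
  n_tiles <- length(train$tiles)
  if (n_tiles < 1) stopf("empty training set")
  dual <- model$config$branch_mode == "dual"
  nc <- model$config$n_classes
  lossfn <- if (config$loss == "softmax") softmax_from_logits else bce_from_logits
  opt <- adam_init(model$params)
  hist <- vector("list", config$max_epochs)
  best <- list(val = Inf, params = model$params, state = model$state)
  for (epoch in seq_len(config$max_epochs)) {
    lr <- config$lr
    if (config$lr_schedule == "step" && epoch >= config$step_epoch)
      lr <- lr * config$step_factor
    perm <- with_seed(child_seed(config$seed, paste0("epoch", epoch)),
                      sample.int(n_tiles))
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    ep_loss <- 0; ep_correct <- 0; ep_valid <- 0
    for (bi in seq_along(batches)) {
      b <- make_batch(train, batches[[bi]], nc, dual, train$tile)
      fw <- net_fwd(model, b$tnS, b$tnA, training = TRUE)
      model$state <- fw$state
      lr_ <- lossfn(fw$logits$x, b$y, b$mask)
      if (!is.finite(lr_$loss))
        stopf("training diverged: non-finite loss at epoch %d (batch %d)",
              epoch, bi)
      grads <- net_bwd(model, fw, lr_$grad)
      st <- adam_step(model$params, grads, opt, lr)
      model$params <- st$params; opt <- st$opt
      ep_loss <- ep_loss + lr_$loss * length(batches[[bi]])
      pred <- max.col(fw$logits$x[b$mask, , drop = FALSE], ties.method = "first")
      ep_correct <- ep_correct + sum(pred == b$labels[b$mask])
      ep_valid <- ep_valid + sum(b$mask)
    }
    row <- list(epoch = epoch, loss = ep_loss / n_tiles,
                accuracy = ep_correct / ep_valid, lr = lr,
                val_loss = NA_real_, val_accuracy = NA_real_)
    if (!is.null(validation)) {
      ev <- evaluate_tiles(model, validation, lossfn)
      row$val_loss <- ev$loss; row$val_accuracy <- ev$accuracy
      if (is.finite(ev$loss) && ev$loss < best$val)
        best <- list(val = ev$loss, params = model$params, state = model$state)
    }
    hist[[epoch]] <- row
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  acc %.4f%s", epoch, row$loss,
                      row$accuracy,
                      if (is.na(row$val_loss)) ""
                      else sprintf("  val_loss %.4f  val_acc %.4f",
                                   row$val_loss, row$val_accuracy)))
  }
  final <- model
  if (!is.null(validation) && is.finite(best$val)) {
    model$params <- best$params
    model$state <- best$state
  }
  structure(list(model = model, final_model = final,
                 history = tibble::as_tibble(do.call(rbind.data.frame, hist)),
                 config = config),
            class = "hsiseg_fit")
}

# Inference-mode loss/accuracy over a tile set (padding + unlabeled masked).
evaluate_tiles <- function(model, tiles, lossfn = bce_from_logits) {
  dual <- model$config$branch_mode == "dual"
  nc <- model$config$n_classes
  tot_loss <- 0; correct <- 0; valid <- 0
  for (i in seq_along(tiles$tiles)) {
    b <- make_batch(tiles, i, nc, dual, tiles$tile)
    fw <- net_fwd(model, b$tnS, b$tnA, training = FALSE)
    l <- lossfn(fw$logits$x, b$y, b$mask)
    tot_loss <- tot_loss + l$loss
    pred <- max.col(fw$logits$x[b$mask, , drop = FALSE], ties.method = "first")
    correct <- correct + sum(pred == b$labels[b$mask])
    valid <- valid + sum(b$mask)
  }
  list(loss = tot_loss / length(tiles$tiles), accuracy = correct / valid)
}

#' @export
print.hsiseg_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<hsiseg_fit> %d epochs; final loss %.4f, accuracy %.4f\n",
              nrow(h), h$loss[nrow(h)], h$accuracy[nrow(h)]))
  invisible(x)
}

#' Predict a label map from tiles
#'
#' Runs the model tile by tile in inference mode, fuses the per-class
#' sigmoid probabilities by per-pixel argmax, strips the reflection padding
#' and mosaics tiles back to scene extent by their recorded origins.
#'
#' @param model an `hsiseg_model` or `hsiseg_fit`.
#' @param tiles a `tile_set`.
#' @return A [label_map()] at the tile set's scene extent; pixels not
#'   covered by `tiles` are 0 (unlabeled).
#' @export
predict_labels <- function(model, tiles) {
  if (inherits(model, "hsiseg_fit")) model <- model$model
  stopifnot(inherits(model, "hsiseg_model"), inherits(tiles, "tile_set"))
  dual <- model$config$branch_mode == "dual"
  per_tile <- lapply(tiles$tiles, function(t) {
    logits <- net_forward(model, t$spectral,
                          if (dual) t$artificial else NULL)
    hw <- dim(logits)[1:2]
    m <- matrix(max.col(matrix(logits, prod(hw), dim(logits)[3]),
                        ties.method = "first"), hw[1], hw[2])
    m
  })
  mos <- mosaic_tiles(tiles, per_tile)
  mos[is.na(mos)] <- 0L
  label_map(round(mos), tiles$scheme)
}
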