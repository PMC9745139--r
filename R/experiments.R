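# Desk-scale ablation experiments on synthetic scenes.
#
# E1 — architecture ablation: plain-convolution U-Net vs the improved
#      network with residual shortcuts off vs the full block.
# E2 — single-channel stacking: PCA alone, then NDVI / Sobel / GLCM stacked
#      onto the spectral input of one branch.
# E3 — dual-branch fusion ladder: PCA | PCA+NDVI | PCA+NDVI+GLCM |
#      PCA+NDVI+GLCM+Sobel as the artificial branch.
#
# Every variant in a run consumes byte-identical tiles, the same split and
# the same seed, so differences are attributable to the architecture or the
# feature set. Whether feature stacking hurts and dual-branch fusion helps
# is an empirical question on synthetic scenes; the tables report it, the
# package does not assert it.

experiment_variants <- function(name) {
  switch(name,
    e1 = list(
      list(id = "plain_unet", block = "plain", residual = FALSE, mode = "single", art = NULL),
      list(id = "separable_no_residual", block = "separable", residual = FALSE, mode = "single", art = NULL),
      list(id = "separable_residual", block = "separable", residual = TRUE, mode = "single", art = NULL)),
    e2 = list(
      list(id = "pca", mode = "single", art = NULL),
      list(id = "pca_ndvi", mode = "single", art = 1L),
      list(id = "pca_ndvi_sobel", mode = "single", art = c(1L, 6L)),
      list(id = "pca_ndvi_sobel_glcm", mode = "single", art = c(1L, 6L, 2:5))),
    e3 = list(
      list(id = "pca", mode = "single", art = NULL),
      list(id = "pca|ndvi", mode = "dual", art = 1L),
      list(id = "pca|ndvi+glcm", mode = "dual", art = c(1L, 2:5)),
      list(id = "pca|ndvi+glcm+sobel", mode = "dual", art = 1:6)),
    stopf("unknown experiment '%s' (e1, e2 or e3)", name))
}

# Subset the artificial channels of every tile; for "stack" mode append them
# to the spectral input instead.
variant_tiles <- function(tiles, art_channels, stack = FALSE) {
  out <- tiles
  out$tiles <- lapply(tiles$tiles, function(t) {
    if (is.null(art_channels)) {
      t$artificial <- NULL
    } else if (stack) {
      t$spectral <- array(c(t$spectral, t$artificial[, , art_channels, drop = FALSE]),
                          dim = c(dim(t$spectral)[1:2],
                                  dim(t$spectral)[3] + length(art_channels)))
      t$artificial <- NULL
    } else {
      t$artificial <- t$artificial[, , art_channels, drop = FALSE]
    }
    t
  })
  out
}

#' Run an ablation experiment on a synthetic scene
#'
#' Simulates one scene, computes PCA scores and the artificial feature
#' stack, tiles and splits once, then trains every variant of the named
#' experiment from the same seed on byte-identical tiles. Variants that
#' diverge are recorded as failed; the others continue.
#'
#' @param name `"e1"`, `"e2"` or `"e3"`.
#' @param spec a [scene_spec()] (default: the desk-scale 256 x 256 x 32
#'   scene with 5 classes).
#' @param config a [train_config()].
#' @param tile tile edge in pixels (default 64).
#' @param channels per-level network widths.
#' @param seed global seed (scene, split, init, shuffling).
#' @param verbose print per-epoch progress.
#' @return An object of class `hsiseg_experiment`: `table` (tibble: one row
#'   per variant with parameter count, overall accuracy, macro F1, group F1
#'   columns) and `runs` (per-variant fits, metrics and histories).
#' @export
run_experiment <- function(name = c("e1", "e2", "e3"), spec = scene_spec(),
                           config = train_config(), tile = 64,
                           channels = c(32, 64, 128, 256, 512),
                           seed = 1L, verbose = FALSE) {
  name <- match.arg(name)
  variants <- experiment_variants(name)
  spec$seed <- as.integer(seed)
  scene <- simulate_scene(spec)
  pca <- fit_pca(scene$cube, k = 6)
  pca_cube <- apply_pca(scene$cube, pca)
  feats <- build_artificial_stack(scene$cube, pca_model = fit_pca(scene$cube, k = 1))
  tiles <- tile_scene(pca_cube, feats, scene$labels, tile = tile)
  split <- split_tiles(tiles, ratio = 0.8, seed = seed)
  runs <- list()
  rows <- list()
  for (v in variants) {
    stack <- name == "e2" && !is.null(v$art)
    tr <- variant_tiles(split$train, v$art, stack = stack)
    te <- variant_tiles(split$test, v$art, stack = stack)
    n_art <- if (is.null(v$art)) NULL else length(v$art)
    in_ch <- if (identical(v$mode, "dual")) c(6L, n_art)
             else 6L + if (stack) n_art else 0L
    cfg <- net_config(channels = channels, in_channels = in_ch,
                      n_classes = n_classes(tiles$scheme),
                      residual = v$residual %||% TRUE,
                      branch_mode = if (identical(v$mode, "dual")) "dual" else "single",
                      block = v$block %||% "separable")
    model <- build_model_impl(cfg, seed = child_seed(seed, v$id))
    fit <- tryCatch(
      train_model(model, tr, config, validation = te, verbose = verbose),
      error = function(e) e)
    if (inherits(fit, "error")) {
      runs[[v$id]] <- list(error = conditionMessage(fit))
      rows[[v$id]] <- tibble::tibble(variant = v$id,
                                     parameters = count_parameters(model),
                                     failed = TRUE, overall_accuracy = NA_real_,
                                     macro_f1 = NA_real_)
      next
    }
    pred <- predict_labels(fit$model, te)
    truth <- truth_from_tiles(te)
    rep <- metrics_report(truth, pred$labels)
    gf1 <- setNames(rep$grouped$metrics$f1,
                    paste0("f1_", gsub("\\s+", "_", tolower(rep$grouped$metrics$class))))
    rows[[v$id]] <- tibble::tibble(
      variant = v$id, parameters = count_parameters(model), failed = FALSE,
      overall_accuracy = rep$overall_accuracy, macro_f1 = rep$macro_f1,
      !!!as.list(gf1))
    runs[[v$id]] <- list(fit = fit, metrics = rep, history = fit$history)
  }
  structure(list(name = name, table = bind_rows_fill(rows), runs = runs,
                 seed = seed),
            class = "hsiseg_experiment")
}

# rbind tibbles whose columns may differ (failed variants lack group-F1
# columns); missing cells become NA.
bind_rows_fill <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  filled <- lapply(rows, function(r) {
    for (m in setdiff(cols, names(r))) r[[m]] <- NA
    r[cols]
  })
  do.call(rbind, filled)
}

# Scene-extent truth restricted to the pixels a tile set covers.
truth_from_tiles <- function(tiles) {
  lab <- mosaic_tiles(tiles, lapply(tiles$tiles, `[[`, "labels"))
  lab[is.na(lab)] <- 0L
  label_map(round(lab), tiles$scheme)
}

#' @export
print.hsiseg_experiment <- function(x, ...) {
  cat(sprintf("<hsiseg_experiment> %s (seed %d)\n", x$name, x$seed))
  print(x$table)
  invisible(x)
}
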