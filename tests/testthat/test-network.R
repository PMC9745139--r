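# Feature-extraction module, U-Net builders, parameter accounting.

test_that("h-swish matches its closed form", {
  expect_equal(h_swish(c(-3, 0, 1, 3)), c(0, 0, 2 / 3, 3))
  grid <- seq(-8, 8, by = 0.25)
  hs <- h_swish(grid)
  expect_equal(hs[grid >= 3], grid[grid >= 3])
  expect_true(all(hs[grid <= -3] == 0))
  mid <- grid > -3 & grid < 3
  expect_equal(hs[mid], grid[mid] * (grid[mid] + 3) / 6)
})

test_that("a feature-extraction module preserves shape and honours the identity shortcut", {
  spec <- module_spec(5, 8)
  x <- withr::with_seed(1, array(rnorm(12 * 12 * 5), c(12, 12, 5)))
  y <- feature_extraction_module(x, spec, fem_params(spec, seed = 2))
  expect_identical(dim(y), c(12L, 12L, 8L))
  expect_true(all(is.finite(y)))
  expect_false(spec$uses_residual)  # channel change: shortcut omitted

  # zeroed convolutions + BN bypass + residual: block reduces to h_swish(x)
  spec_r <- module_spec(5, 5, residual = TRUE)
  expect_true(spec_r$uses_residual)
  y0 <- feature_extraction_module(x, spec_r, fem_params(spec_r, init = "zero"),
                                  bn_identity = TRUE)
  expect_equal(y0, h_swish(x), tolerance = 1e-12)
})

test_that("module parameter counts follow the closed form and undercut plain convolution", {
  expect_identical(module_spec(32, 32)$param_count, 1376L)  # 9*32 + 32*32 + 2*32
  expect_identical(module_spec(32, 32, residual = FALSE)$param_count, 1376L)
  expect_gt(32 * 32 * 9, module_spec(32, 32)$param_count)  # plain 3x3 = 9216
  # doubling widths roughly quadruples the pointwise-dominated count
  expect_equal(module_spec(64, 64)$param_count,
               9 * 64 + 64 * 64 + 2 * 64)
})

test_that("the residual toggle never changes the parameter count (single and dual)", {
  for (mode in c("single", "dual")) {
    in_ch <- if (mode == "dual") c(6, 6) else 6
    on <- net_config(in_channels = in_ch, n_classes = 5, residual = TRUE,
                     branch_mode = mode)
    off <- net_config(in_channels = in_ch, n_classes = 5, residual = FALSE,
                      branch_mode = mode)
    builder <- if (mode == "dual") build_dual_branch else build_single_branch
    expect_identical(count_parameters(builder(on, seed = 1)),
                     count_parameters(builder(off, seed = 1)))
  }
})

test_that("the separable network is smaller than a plain U-Net; dual is larger than single", {
  sep <- build_single_branch(net_config(in_channels = 6, n_classes = 5),
                             seed = 1)
  plain <- build_single_branch(net_config(in_channels = 6, n_classes = 5,
                                          block = "plain"), seed = 1)
  expect_lt(count_parameters(sep), count_parameters(plain))
  dual <- build_dual_branch(net_config(in_channels = c(6, 6), n_classes = 5,
                                       branch_mode = "dual"), seed = 1)
  expect_gt(count_parameters(dual), count_parameters(sep))
})

test_that("parameter totals match an independent closed-form sum", {
  ch <- c(4, 6, 8, 10, 12)
  cfg <- tiny_config(n_classes = 3)
  m <- build_single_branch(cfg, seed = 1)
  fem_n <- function(ci, co) 9 * ci + ci * co + 2 * co
  widths <- c(6, ch)
  expected <- 0
  for (l in 1:5) expected <- expected + fem_n(widths[l], ch[l]) + fem_n(ch[l], ch[l])
  for (l in 1:4) expected <- expected + (ch[l + 1] * ch[l] + ch[l]) +  # up pw + bias
    fem_n(2 * ch[l], ch[l]) + fem_n(ch[l], ch[l])
  expected <- expected + ch[1] * 3 + 3  # head
  expect_identical(count_parameters(m), as.integer(expected))
})

test_that("forward passes satisfy the shape contracts", {
  x <- withr::with_seed(3, array(rnorm(64 * 64 * 6), c(64, 64, 6)))
  m1 <- build_single_branch(tiny_config(n_classes = 3), seed = 2)
  lg <- net_forward(m1, x)
  expect_identical(dim(lg), c(64L, 64L, 3L))
  m2 <- build_dual_branch(tiny_config("dual", in_channels = c(6, 6),
                                      n_classes = 3), seed = 2)
  lg2 <- net_forward(m2, x, x)
  expect_identical(dim(lg2), c(64L, 64L, 3L))
  expect_true(all(is.finite(lg2)))
  bad <- withr::with_seed(3, array(rnorm(60 * 60 * 6), c(60, 60, 6)))
  expect_error(net_forward(m1, bad), "not divisible")
  expect_error(net_forward(m2, x, withr::with_seed(1, array(rnorm(32 * 32 * 6), c(32, 32, 6)))),
               "disagree")
  expect_error(net_forward(m2, x), "both inputs")
})

test_that("the artificial branch is live: zeroing it changes the output", {
  m <- build_dual_branch(tiny_config("dual", in_channels = c(6, 6),
                                     n_classes = 3), seed = 4)
  x <- withr::with_seed(5, array(rnorm(32 * 32 * 6), c(32, 32, 6)))
  a <- withr::with_seed(6, array(rnorm(32 * 32 * 6), c(32, 32, 6)))
  out1 <- net_forward(m, x, a)
  out2 <- net_forward(m, x, a * 0)
  expect_gt(max(abs(out1 - out2)), 1e-6)
  # deterministic in inference mode
  expect_identical(out1, net_forward(m, x, a))
})

test_that("forward pass commutes with horizontal flips (kernels mirrored alongside)", {
  # With fixed random weights a convolution is direction-sensitive, so the
  # equivariance pairs the flipped input with the kernel-mirrored model;
  # any asymmetric padding, pooling or upsampling stage would break it.
  for (mode in c("single", "dual")) {
    in_ch <- if (mode == "dual") c(6, 6) else 6
    builder <- if (mode == "dual") build_dual_branch else build_single_branch
    for (block in c("separable", "plain")) {
      m <- builder(tiny_config(mode, in_channels = in_ch, n_classes = 3,
                               block = block), seed = 8)
      mf <- flip_model_lr(m)
      x <- withr::with_seed(7, array(rnorm(32 * 32 * 6), c(32, 32, 6)))
      a <- withr::with_seed(8, array(rnorm(32 * 32 * 6), c(32, 32, 6)))
      out <- if (mode == "dual") net_forward(m, x, a) else net_forward(m, x)
      out_f <- if (mode == "dual") net_forward(mf, flip_lr(x), flip_lr(a))
               else net_forward(mf, flip_lr(x))
      expect_equal(out_f, flip_lr(out), tolerance = 1e-5)
    }
  }
})

test_that("analytic gradients of the full dual network match finite differences", {
  cfg <- net_config(channels = c(3, 4, 5, 6, 7), in_channels = c(2, 2),
                    n_classes = 2, branch_mode = "dual")
  m <- build_dual_branch(cfg, seed = 7)
  H <- 16
  xS <- withr::with_seed(1, array(rnorm(H * H * 2), c(H, H, 2)))
  xA <- withr::with_seed(2, array(rnorm(H * H * 2), c(H, H, 2)))
  lab <- withr::with_seed(3, matrix(sample(0:2, H * H, TRUE), H, H))
  oh <- one_hot_encode(lab, 2)
  tnS <- hsiseg:::batch_tensor(list(xS)); tnA <- hsiseg:::batch_tensor(list(xA))
  loss_of <- function(model) {
    fw <- hsiseg:::net_fwd(model, tnS, tnA, training = TRUE)
    hsiseg:::bce_from_logits(fw$logits$x, oh$y, oh$mask)$loss
  }
  fw <- hsiseg:::net_fwd(m, tnS, tnA, training = TRUE)
  lr <- hsiseg:::bce_from_logits(fw$logits$x, oh$y, oh$mask)
  gr <- hsiseg:::net_bwd(m, fw, lr$grad)
  eps <- 1e-5
  for (nm in c("encA1_m1_dw", "encB2_m1_gamma", "fuse3_pw", "up2_pw",
               "dec1_m2_beta", "head_w")) {
    p <- m$params[[nm]]
    ks <- withr::with_seed(10, sample(length(p), min(3, length(p))))
    for (k in ks) {
      mp <- m; mp$params[[nm]][k] <- p[k] + eps
      mm <- m; mm$params[[nm]][k] <- p[k] - eps
      fd <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(gr[[nm]][k], fd, tolerance = 1e-4)
    }
  }
})
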