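# Multiscale 3D convolution token extractor.

test_that("direct 3D convolution agrees with an im2col + gemm oracle", {
  set.seed(3)
  x <- array(rnorm(12 * 10 * 5), c(12, 10, 5))
  for (k in c(1L, 3L, 5L)) {
    Wm <- matrix(rnorm(4 * k^3), 4, k^3)
    direct <- windmri:::cpp_conv3d_same(as.numeric(x), 12L, 10L, 5L, Wm, k)
    col <- windmri:::cpp_im2col3d(as.numeric(x), 12L, 10L, 5L, k)
    expect_equal(direct, col %*% t(Wm), tolerance = 1e-12)
  }
})

test_that("a branch yields out_tokens rows of (side/8)^2 features", {
  cfg <- mhmc_config(kernels = c(3), mid_channels = c(3), out_tokens = c(64),
                     input_side = 32)
  p <- windmri:::init_branch_params(3, 3, 64)
  x <- array(rnorm(32 * 32 * 5), c(32, 32, 5))
  out <- branch_forward(x, 3, p, cfg)
  expect_identical(dim(out$tokens), c(64L, 16L))  # (32/8)^2 = 16
})

test_that("an all-zero input maps to all-zero tokens", {
  cfg <- tiny_model_config()$mhmc
  params <- windmri:::init_mhmc_params(cfg, seed = 4)
  # zero shift parameters so normalization cannot re-introduce offsets
  params <- lapply(params, function(b) { b$bd[] <- 0; b$bp[] <- 0
                                         b$be1[] <- 0; b$be2[] <- 0; b })
  out <- mhmc_forward(array(0, c(16, 16, 5)), params, cfg)
  expect_true(all(out$tokens == 0))
})

test_that("default configuration produces the 448 x 784 token matrix", {
  cfg <- default_model_config()
  m <- build_model(cfg, seed = 1)
  x <- array(rnorm(224 * 224 * 5), c(224, 224, 5))
  out <- mhmc_forward(x, m$params$mhmc, cfg$mhmc)
  expect_identical(dim(out$tokens), c(448L, 784L))
})

test_that("token blocks concatenate in branch order", {
  cfg <- tiny_model_config()$mhmc
  params <- windmri:::init_mhmc_params(cfg, seed = 5)
  x <- tiny_input(2)
  full <- mhmc_forward(x, params, cfg)$tokens
  b1 <- branch_forward(x, 1, params[[1]], cfg)$tokens
  b3 <- branch_forward(x, 3, params[[2]], cfg)$tokens
  b5 <- branch_forward(x, 5, params[[3]], cfg)$tokens
  expect_equal(full, rbind(b1, b3, b5))
  expect_equal(full[3:5, ], b3)  # permuting blocks relocates, not alters
})

test_that("identical inputs give identical token matrices", {
  cfg <- tiny_model_config()$mhmc
  params <- windmri:::init_mhmc_params(cfg, seed = 6)
  x <- tiny_input(3)
  expect_identical(mhmc_forward(x, params, cfg)$tokens,
                   mhmc_forward(x, params, cfg)$tokens)
})

test_that("depthwise-separable layer 2 has fewer parameters than a dense conv", {
  for (i in seq_along(c(1, 3, 5))) {
    cfg <- mhmc_config()
    k <- cfg$kernels[i]; c1 <- cfg$mid_channels[i]; c2 <- cfg$out_tokens[i]
    separable <- k^3 * c1 + c1 * c2       # depthwise + pointwise weights
    dense <- k^3 * c1 * c2                # full 3D convolution
    if (k > 1) expect_lt(separable, dense)
  }
})

test_that("the k = 5 branch has a wider receptive field than k = 1", {
  cfg <- mhmc_config(kernels = c(1, 3, 5), mid_channels = c(2, 2, 2),
                     out_tokens = c(2, 2, 2), input_side = 16)
  params <- windmri:::init_mhmc_params(cfg, seed = 7)
  base <- array(0, c(16, 16, 5))
  probe <- base; probe[8, 8, 3] <- 1
  # first-layer linear response (pre-normalization) isolates the kernel
  # footprint: count voxels reached by the impulse
  reach <- function(k, W1) {
    z <- windmri:::cpp_conv3d_same(as.numeric(probe), 16L, 16L, 5L, W1, k)
    sum(rowSums(abs(z)) > 0)
  }
  r1 <- reach(1L, params[[1]]$W1)
  r5 <- reach(5L, params[[3]]$W1)
  expect_gt(r5, r1)
  expect_identical(r1, 1L)
})

test_that("output units ignore input changes outside their receptive field", {
  cfg <- mhmc_config(kernels = 3, mid_channels = 2, out_tokens = 2,
                     input_side = 16)
  p <- list(windmri:::init_branch_params(3, 2, 2))
  x1 <- tiny_input(4)
  x2 <- x1
  x2[16, 16, 5] <- x2[16, 16, 5] + 100  # far corner
  t1 <- branch_forward(x1, 3, p[[1]], cfg)$tokens
  t2 <- branch_forward(x2, 3, p[[1]], cfg)$tokens
  # feature 1 corresponds to the opposite spatial corner after reduction;
  # instance normalization is global, so compare pre-normalization layer 1
  z1 <- windmri:::cpp_conv3d_same(as.numeric(x1), 16L, 16L, 5L, p[[1]]$W1, 3L)
  z2 <- windmri:::cpp_conv3d_same(as.numeric(x2), 16L, 16L, 5L, p[[1]]$W1, 3L)
  changed <- which(rowSums(abs(z1 - z2)) > 0)
  vox <- arrayInd(changed, c(16L, 16L, 5L))
  expect_true(all(vox[, 1] >= 15 & vox[, 2] >= 15 & vox[, 3] >= 4))
  expect_identical(dim(t1), dim(t2))
})

test_that("branch gradients pass a finite-difference check (mhmc-only model)", {
  model <- build_model(tiny_model_config("mhmc_only"), seed = 8)
  worst <- check_gradients(model, tiny_input(5), y = 1)
  expect_lt(worst, 1e-4)
})
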