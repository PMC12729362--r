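#' Configuration of the multi-head mixed 3D convolution token extractor
#'
#' Three parallel dual-layer 3D convolution branches with kernel sizes 1, 3
#' and 5 turn the canonical `224 x 224 x 5` input into a token matrix. Each
#' branch applies: (1) a standard 3D convolution, per-sample channel
#' normalization, ReLU and `2 x 2 x 2` max pooling; (2) a depthwise 3D
#' convolution with spatial/phase stride 2, a `1 x 1 x 1` pointwise
#' convolution, normalization, ReLU and `2 x 2 x 1` max pooling. The spatial
#' side shrinks by 8 (224 to 28) and the phase axis collapses, so each output
#' channel becomes one token of `28^2 = 784` features. With the default token
#' allocation (64, 128, 256) the concatenated matrix is `448 x 784`.
#'
#' @param kernels Cubic kernel edge per branch.
#' @param mid_channels First-layer channel count per branch.
#' @param out_tokens Output channels (= token rows) per branch.
#' @param input_side Input pixels per side.
#' @param phases Input phase count.
#' @param bn_layer2 Normalize after the pointwise convolution as well.
#' @return An `mhmc_config`.
#' @export
mhmc_config <- function(kernels = c(1, 3, 5),
                        mid_channels = c(16, 32, 64),
                        out_tokens = c(64, 128, 256),
                        input_side = 224, phases = 5,
                        bn_layer2 = TRUE) {
  assert_that(all(kernels %in% c(1, 3, 5)), "kernels must be in {1,3,5}")
  assert_that(length(kernels) == length(mid_channels) &&
                length(kernels) == length(out_tokens),
              "per-branch settings must have equal lengths")
  assert_that(all(out_tokens > 0), "out_tokens must be positive")
  structure(list(kernels = as.integer(kernels),
                 mid_channels = as.integer(mid_channels),
                 out_tokens = as.integer(out_tokens),
                 input_side = as.integer(input_side),
                 phases = as.integer(phases),
                 bn_layer2 = isTRUE(bn_layer2)),
            class = "mhmc_config")
}

# Feature dimension per token implied by the config (spatial side / 8)^2.
mhmc_feature_dim <- function(cfg) {
  (cfg$input_side %/% 8L)^2
}

init_branch_params <- function(k, c1, c2) {
  # no bias on the first convolution: the following per-channel
  # normalization cancels any constant channel shift
  list(W1 = init_weight(c1, k^3, fan_in = k^3),
       g1 = rep(1, c1), be1 = numeric(c1),
       Wd = matrix(rnorm(k^3 * c1, 0, sqrt(2 / k^3)), k^3, c1),
       bd = numeric(c1),
       Wp = init_weight(c2, c1, fan_in = c1),
       bp = numeric(c2),
       g2 = rep(1, c2), be2 = numeric(c2))
}

init_mhmc_params <- function(cfg, seed = 1L) {
  with_seed(seed, {
    lapply(seq_along(cfg$kernels), function(i) {
      init_branch_params(cfg$kernels[i], cfg$mid_channels[i], cfg$out_tokens[i])
    })
  })
}

#' Forward pass of one convolution branch
#'
#' @param x `H x W x T` numeric array (single-channel multiphase input).
#' @param k Cubic kernel edge.
#' @param params Branch parameter list (see `init_branch_params`).
#' @param cfg The `mhmc_config`.
#' @param keep_cache Retain intermediates for the backward pass.
#' @return List with `tokens` (`out_tokens x features`) and `cache`.
#' @export
branch_forward <- function(x, k, params, cfg = mhmc_config(),
                           keep_cache = FALSE) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; D <- d[3]
  xv <- as.numeric(x)
  z1 <- cpp_conv3d_same(xv, H, W, D, params$W1, k)
  n1 <- instnorm_fwd(z1, params$g1, params$be1)
  a1 <- relu_fwd(n1$out)
  p1 <- cpp_maxpool3d(a1$out, H, W, D, 2L, 2L, 2L)
  d1 <- p1$dims
  dw <- cpp_depthwise3d(p1$out, d1[1], d1[2], d1[3], params$Wd, params$bd,
                        k, 2L, 2L, 2L)
  d2 <- dw$dims
  z2 <- col_add(dw$out %*% t(params$Wp), params$bp)
  if (cfg$bn_layer2) {
    n2 <- instnorm_fwd(z2, params$g2, params$be2)
    pre2 <- n2$out
  } else {
    n2 <- NULL
    pre2 <- z2
  }
  a2 <- relu_fwd(pre2)
  p2 <- cpp_maxpool3d(a2$out, d2[1], d2[2], d2[3], 2L, 2L, 1L)
  tokens <- t(p2$out)
  cache <- if (keep_cache) {
    list(xv = xv, n1 = n1, a1 = a1,
         p1 = p1, in_dims = d, d1 = d1, dw_in = p1$out, dw = dw, d2 = d2,
         n2 = n2, a2 = a2, p2 = p2, k = k)
  } else NULL
  list(tokens = tokens, cache = cache)
}

# Backward pass of one branch. dtokens: (out_tokens x features). Returns
# parameter gradients; optionally captures the gradient at the layer-1 ReLU
# output (for Grad-CAM).
branch_backward <- function(dtokens, cache, params, cfg,
                            capture_act1 = FALSE) {
  d2 <- cache$d2
  dp2 <- cpp_maxpool3d_bwd(t(dtokens), cache$p2$idx, prod(d2))
  da2 <- relu_bwd(dp2, cache$a2)
  if (cfg$bn_layer2) {
    nb <- instnorm_bwd(da2, cache$n2, params$g2)
    dz2 <- nb$dx; dg2 <- nb$dgamma; dbe2 <- nb$dbeta
  } else {
    dz2 <- da2; dg2 <- numeric(length(params$g2)); dbe2 <- dg2
  }
  dWp <- crossprod(dz2, cache$dw$out)
  dbp <- colSums(dz2)
  ddw_out <- dz2 %*% params$Wp
  d1 <- cache$d1
  bw <- cpp_depthwise3d_bwd(ddw_out, cache$dw_in, d1[1], d1[2], d1[3],
                            params$Wd, cache$k, 2L, 2L, 2L)
  dp1 <- cpp_maxpool3d_bwd(bw$dx, cache$p1$idx, prod(cache$in_dims))
  da1 <- relu_bwd(dp1, cache$a1)
  nb1 <- instnorm_bwd(da1, cache$n1, params$g1)
  dz1 <- nb1$dx
  d0 <- cache$in_dims
  dW1 <- cpp_conv3d_same_dw(cache$xv, dz1, d0[1], d0[2], d0[3], cache$k)
  grads <- list(W1 = dW1, g1 = nb1$dgamma, be1 = nb1$dbeta,
                Wd = bw$dw, bd = as.numeric(bw$db),
                Wp = dWp, bp = dbp, g2 = dg2, be2 = dbe2)
  list(grads = grads, dact1 = if (capture_act1) da1 else NULL)
}

#' Forward pass of the full multiscale token extractor
#'
#' Runs the three branches and concatenates their token blocks along the
#' token axis in kernel order.
#'
#' @param x `H x W x T` input array (canonically `224 x 224 x 5`).
#' @param params Parameter list from `init_mhmc_params`.
#' @param cfg An [mhmc_config()].
#' @param keep_cache Retain intermediates for the backward pass.
#' @return List with `tokens` (default `448 x 784`) and per-branch `caches`.
#' @export
mhmc_forward <- function(x, params, cfg = mhmc_config(), keep_cache = FALSE) {
  if (inherits(x, "phase_stack")) x <- x$values
  outs <- lapply(seq_along(cfg$kernels), function(i) {
    branch_forward(x, cfg$kernels[i], params[[i]], cfg, keep_cache)
  })
  tokens <- do.call(rbind, lapply(outs, `[[`, "tokens"))
  list(tokens = tokens, caches = lapply(outs, `[[`, "cache"))
}

mhmc_backward <- function(dtokens, caches, params, cfg,
                          capture_branch = 0L) {
  offs <- c(0, cumsum(cfg$out_tokens))
  grads <- vector("list", length(cfg$kernels))
  dact1 <- NULL
  for (i in seq_along(cfg$kernels)) {
    rows <- (offs[i] + 1):offs[i + 1]
    bb <- branch_backward(dtokens[rows, , drop = FALSE], caches[[i]],
                          params[[i]], cfg,
                          capture_act1 = identical(i, as.integer(capture_branch)))
    grads[[i]] <- bb$grads
    if (!is.null(bb$dact1)) dact1 <- bb$dact1
  }
  list(grads = grads, dact1 = dact1)
}
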