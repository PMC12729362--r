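# Fused window attention: partitioning, Q/K/V construction, attention,
# fusion, and end-to-end gradients.

naive_dense_attention <- function(Q, K, V, scale) {
  # direct transcription of softmax(Q K' * scale) V, row by row
  out <- matrix(0, nrow(Q), ncol(V))
  for (i in seq_len(nrow(Q))) {
    s <- as.numeric(Q[i, ] %*% t(K)) * scale
    e <- exp(s - max(s))
    p <- e / sum(e)
    out[i, ] <- as.numeric(p %*% V)
  }
  out
}

test_that("the window count follows F = (T - W)/S + 1 and rejects non-integral specs", {
  expect_identical(window_spec(W = 64, S = 48, L = 8, T = 448)$F, 9L)
  expect_error(window_spec(W = 64, S = 47, T = 448), "not divisible")
  # degenerate single window: W = T
  sp <- window_spec(W = 448, S = 1, L = 0, T = 448)
  expect_identical(sp$F, 1L)
  # property over a grid of (W, S)
  for (W in c(16, 32, 64, 112)) {
    for (S in c(8, 16, 24, 48)) {
      T <- 448
      if ((T - W) %% S == 0) {
        expect_identical(window_spec(W, S, 4, T)$F, as.integer((T - W) / S + 1))
      } else {
        expect_error(window_spec(W, S, 4, T), "not divisible")
      }
    }
  }
})

test_that("windows tile the sequence and fringes clamp at the edges", {
  sp <- window_spec(W = 64, S = 48, L = 8, T = 448)
  tokens <- matrix(rnorm(448 * 4), 448, 4)
  wins <- partition_windows(tokens, sp)
  expect_length(wins, 9)
  expect_identical(wins[[1]]$indices$base, 1:64)
  expect_identical(wins[[9]]$indices$base, 385:448)
  # every token appears in at least one base window
  covered <- sort(unique(unlist(lapply(wins, function(w) w$indices$base))))
  expect_identical(covered, 1:448)
  # boundary fringes repeat the edge token
  expect_identical(wins[[1]]$indices$left, rep(1L, 8))
  expect_identical(wins[[9]]$indices$right, rep(448L, 8))
  expect_identical(wins[[2]]$indices$left, 41:48)
  expect_error(partition_windows(tokens[1:100, ], sp), "does not match")
})

test_that("Q/K/V row counts follow the context/fringe/base construction", {
  N <- 784
  sp <- window_spec(W = 64, S = 48, L = 8, T = 448)
  tokens <- matrix(rnorm(448 * N), 448, N)
  win <- partition_windows(tokens, sp)[[2]]
  ctx <- matrix(rnorm(N), 1, N)
  Wq <- diag(N); Wk <- diag(N)
  qkv <- build_qkv(win, ctx, Wq, Wk)
  expect_identical(dim(qkv$Q), c(65L, 784L))   # 1 + W
  expect_identical(dim(qkv$K), c(81L, 784L))   # 1 + W + 2L
  expect_identical(qkv$V, qkv$K)               # shared key/value projection

  # identity projections, zero context: base rows pass through
  qkv0 <- build_qkv(win, matrix(0, 1, N), Wq, Wk)
  expect_equal(qkv0$Q[-1, ], win$base, tolerance = 1e-12)

  # L = 0 collapses K to the Q row count
  sp0 <- window_spec(W = 64, S = 48, L = 0, T = 448)
  win0 <- partition_windows(tokens, sp0)[[1]]
  qkv00 <- build_qkv(win0, ctx, Wq, Wk)
  expect_identical(nrow(qkv00$K), nrow(qkv00$Q))
})

test_that("attention rows are softmax-normalized convex combinations", {
  cfg <- attention_config(n_heads = 2, depth = 1, feature_dim = 8,
                          ff_expansion = 1)
  set.seed(9)
  Q <- matrix(rnorm(5 * 8), 5, 8)
  K <- matrix(rnorm(7 * 8), 7, 8)
  att <- window_attention(Q, K, K, cfg, keep_cache = TRUE)
  for (h in att$cache$heads) {
    expect_equal(rowSums(h$P), rep(1, 5), tolerance = 1e-12)
  }
  # constant value rows: every output row equals that value vector
  v <- rnorm(8)
  Vc <- matrix(v, 7, 8, byrow = TRUE)
  attc <- window_attention(Q, K, Vc, cfg)
  expect_equal(attc$out, matrix(v, 5, 8, byrow = TRUE), tolerance = 1e-12)
  expect_error(window_attention(Q * NA, K, K, cfg), "non-finite")
})

test_that("single-window attention equals a brute-force dense oracle", {
  set.seed(10)
  tokens <- matrix(rnorm(16 * 8), 16, 8)
  cfg <- attention_config(n_heads = 1, depth = 1, feature_dim = 8,
                          ff_expansion = 1)
  att <- window_attention(tokens, tokens, tokens, cfg)
  oracle <- naive_dense_attention(tokens, tokens, tokens, 1 / sqrt(8))
  expect_equal(att$out, oracle, tolerance = 1e-5)

  # the literal 1/d_i scaling flag
  cfg_raw <- attention_config(n_heads = 1, depth = 1, feature_dim = 8,
                              ff_expansion = 1, raw_di_scaling = TRUE)
  att_raw <- window_attention(tokens, tokens, tokens, cfg_raw)
  expect_equal(att_raw$out, naive_dense_attention(tokens, tokens, tokens, 1 / 8),
               tolerance = 1e-5)
  expect_false(isTRUE(all.equal(att$out, att_raw$out)))

  # multi-head: per-head oracle on column blocks
  cfg2 <- attention_config(n_heads = 2, depth = 1, feature_dim = 8,
                           ff_expansion = 1)
  att2 <- window_attention(tokens, tokens, tokens, cfg2)
  for (h in 1:2) {
    cols <- ((h - 1) * 4 + 1):(h * 4)
    expect_equal(att2$out[, cols],
                 naive_dense_attention(tokens[, cols], tokens[, cols],
                                       tokens[, cols], 1 / sqrt(4)),
                 tolerance = 1e-5)
  }
})

test_that("window fusion is the arithmetic mean, order-invariant", {
  cmat <- rbind(c(0, 2), c(2, 0))
  expect_equal(fuse_windows(cmat)$pre_norm, c(1, 1))
  expect_equal(fuse_windows(cmat[2:1, ])$pre_norm, c(1, 1))
  same <- matrix(5.5, 4, 3)
  expect_equal(fuse_windows(same)$pre_norm, rep(5.5, 3))
  expect_error(fuse_windows(matrix(0, 0, 3)), "empty")
  # with layer normalization appended
  ln <- list(g = rep(1, 2), b = c(0, 0))
  fo <- fuse_windows(cmat, ln = ln)
  expect_equal(fo$pre_norm, c(1, 1))
  expect_equal(fo$fused, c(0, 0))  # equal components normalize to zero
})

test_that("the attention stack is deterministic and emits an N-vector", {
  cfg <- tiny_model_config()
  params <- windmri:::init_fwam_params(cfg$attn, cfg$spec, seed = 3)
  tokens <- matrix(rnorm(9 * 4), 9, 4)
  a <- fwam_forward(tokens, params, cfg$spec, cfg$attn)
  b <- fwam_forward(tokens, params, cfg$spec, cfg$attn)
  expect_identical(a$fused, b$fused)
  expect_length(a$fused, 4)
  expect_identical(dim(a$ctx), c(3L, 4L))
})

test_that("full-model gradients pass a finite-difference check", {
  model <- build_model(tiny_model_config("full", depth = 2), seed = 9)
  worst <- check_gradients(model, tiny_input(6), y = 0)
  expect_lt(worst, 1e-4)
})

test_that("context-token feed-forward variant also passes gradient checks", {
  model <- build_model(tiny_model_config("full", ff_tokens = "context"), seed = 10)
  worst <- check_gradients(model, tiny_input(7), y = 1)
  expect_lt(worst, 1e-4)
})

test_that("attention-only variant gradients are exact, including the shared token", {
  model <- build_model(tiny_model_config("fwam_only"), seed = 11)
  x <- tiny_input(8)
  worst <- check_gradients(model, x, y = 1)
  expect_lt(worst, 1e-4)
  # the shared auxiliary token is genuinely learnable: nonzero gradient
  fw <- model_forward(model, x, keep_cache = TRUE)
  g <- windmri:::model_backward(model, fw$cache, fw$prob - 1)$grads
  expect_gt(sum(abs(g$fwam$ctx0)), 0)
})
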