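#' Window specification for fused window attention
#'
#' Partitions a token sequence of length `T` into `F = (T - W)/S + 1` windows
#' of `W` tokens with stride `S`; each window carries a fringe of `L` tokens
#' on both sides (edge-clamped at the sequence boundaries). Non-integral `F`
#' is a configuration error, never silent truncation.
#'
#' @param W Window length in tokens.
#' @param S Stride between adjacent windows.
#' @param L Fringe length per side.
#' @param T Sequence length (default 448).
#' @return A `window_spec` with the window count `F`.
#' @export
window_spec <- function(W = 64, S = 48, L = 8, T = 448) {
  assert_that(W >= 1 && W <= T, "window length must lie in [1, T]")
  assert_that(S >= 1, "stride must be positive")
  assert_that(L >= 0, "fringe length must be nonnegative")
  if ((T - W) %% S != 0) {
    rlang::abort(sprintf(
      "invalid window spec: (T - W) = %d is not divisible by S = %d", T - W, S))
  }
  F <- (T - W) %/% S + 1L
  structure(list(W = as.integer(W), S = as.integer(S), L = as.integer(L),
                 T = as.integer(T), F = as.integer(F)),
            class = "window_spec")
}

# 1-based base and (clamped) fringe row indices of window i.
window_indices <- function(spec, i) {
  start <- (i - 1L) * spec$S + 1L
  base <- start:(start + spec$W - 1L)
  left <- if (spec$L > 0) pmax(1L, (start - spec$L):(start - 1L)) else integer(0)
  right <- if (spec$L > 0) {
    pmin(spec$T, (start + spec$W):(start + spec$W + spec$L - 1L))
  } else integer(0)
  list(base = base, left = left, right = right)
}

#' Partition a token sequence into overlapping windows
#'
#' @param tokens `T x N` token matrix.
#' @param spec A [window_spec()].
#' @return List of `F` window-token lists, each with `base` (`W x N`),
#'   `left` and `right` fringes (`L x N`, edge-clamped) and the row indices.
#' @export
partition_windows <- function(tokens, spec) {
  assert_that(nrow(tokens) == spec$T,
              "token count does not match the window spec")
  lapply(seq_len(spec$F), function(i) {
    idx <- window_indices(spec, i)
    list(base = tokens[idx$base, , drop = FALSE],
         left = tokens[idx$left, , drop = FALSE],
         right = tokens[idx$right, , drop = FALSE],
         indices = idx)
  })
}

#' Attention configuration
#'
#' @param n_heads Attention heads; must divide `feature_dim`.
#' @param depth Number of transformer blocks.
#' @param feature_dim Token feature dimension `N` (default 784).
#' @param ff_expansion Feed-forward hidden width as a multiple of `N`.
#' @param ff_tokens Apply the feed-forward to `"all"` tokens or only the
#'   per-window `"context"` tokens (same parameter count either way).
#' @param raw_di_scaling If `TRUE`, scale attention scores by `1/d_i`
#'   (the literal printed form) instead of the standard `1/sqrt(d_i)`.
#' @return An `attention_config`.
#' @export
attention_config <- function(n_heads = 8, depth = 3, feature_dim = 784,
                             ff_expansion = 6, ff_tokens = c("all", "context"),
                             raw_di_scaling = FALSE) {
  ff_tokens <- match.arg(ff_tokens)
  assert_that(feature_dim %% n_heads == 0, "n_heads must divide feature_dim")
  assert_that(depth >= 1, "depth must be at least 1")
  structure(list(n_heads = as.integer(n_heads), depth = as.integer(depth),
                 feature_dim = as.integer(feature_dim),
                 ff_expansion = ff_expansion, ff_tokens = ff_tokens,
                 raw_di_scaling = isTRUE(raw_di_scaling)),
            class = "attention_config")
}

init_fwam_params <- function(cfg, spec, seed = 1L) {
  N <- cfg$feature_dim
  E <- round(cfg$ff_expansion * N)
  with_seed(seed, {
    blocks <- lapply(seq_len(cfg$depth), function(b) {
      list(Wq = init_weight(N, N), bq = numeric(N),
           Wk = init_weight(N, N), bk = numeric(N),
           Wo = init_weight(N, N), bo = numeric(N),
           ln1_g = rep(1, N), ln1_b = numeric(N),
           ln2_g = rep(1, N), ln2_b = numeric(N),
           Wf1 = init_weight(E, N), bf1 = numeric(E),
           Wf2 = init_weight(N, E), bf2 = numeric(N))
    })
    list(blocks = blocks,
         ctx0 = rnorm(N, 0, 0.02),
         lnf_g = rep(1, N), lnf_b = numeric(N))
  })
}

#' Build query/key/value matrices for one window
#'
#' The query stacks the context token over the base tokens (`(1 + W) x N`);
#' the key stacks context, left fringe, base and right fringe
#' (`(1 + W + 2L) x N`). Per the module's formulation the value matrix shares
#' the key projection: `V = K`.
#'
#' @param win A window-token list from [partition_windows()].
#' @param context `1 x N` context/auxiliary token for this window.
#' @param Wq,bq,Wk,bk Projection parameters (`N x N` weights; length-`N`
#'   biases, zero if omitted).
#' @return List with `Q`, `K`, `V`.
#' @export
build_qkv <- function(win, context, Wq, Wk, bq = NULL, bk = NULL) {
  N <- ncol(win$base)
  bq <- bq %||% numeric(N)
  bk <- bk %||% numeric(N)
  q_in <- rbind(context, win$base)
  k_in <- rbind(context, win$left, win$base, win$right)
  Q <- col_add(q_in %*% t(Wq), bq)
  K <- col_add(k_in %*% t(Wk), bk)
  list(Q = Q, K = K, V = K)
}

#' Multi-head scaled dot-product attention for one window
#'
#' Splits features into `n_heads` contiguous groups; per head computes
#' `softmax(Q K' * scale) V` and concatenates the heads. The default scale is
#' `1/sqrt(d_i)` with `d_i` the per-head feature dimension.
#'
#' @param Q,K,V Projected token matrices (equal feature dimension).
#' @param cfg An [attention_config()].
#' @param keep_cache Retain softmax maps for the backward pass.
#' @return List with `out` (same row count as `Q`) and `cache`.
#' @export
window_attention <- function(Q, K, V, cfg = attention_config(),
                             keep_cache = FALSE) {
  assert_that(all(is.finite(Q)) && all(is.finite(K)) && all(is.finite(V)),
              "non-finite attention inputs")
  N <- ncol(Q)
  h <- cfg$n_heads
  dh <- N %/% h
  scale <- if (cfg$raw_di_scaling) 1 / dh else 1 / sqrt(dh)
  out <- matrix(0, nrow(Q), N)
  caches <- if (keep_cache) vector("list", h) else NULL
  for (j in seq_len(h)) {
    colsj <- ((j - 1) * dh + 1):(j * dh)
    Qh <- Q[, colsj, drop = FALSE]
    Kh <- K[, colsj, drop = FALSE]
    Vh <- V[, colsj, drop = FALSE]
    P <- softmax_rows(tcrossprod(Qh, Kh) * scale)
    out[, colsj] <- P %*% Vh
    if (keep_cache) caches[[j]] <- list(P = P, Qh = Qh, Kh = Kh, Vh = Vh)
  }
  list(out = out, cache = list(heads = caches, scale = scale, dh = dh))
}

window_attention_bwd <- function(dout, cache, cfg) {
  h <- cfg$n_heads
  dh <- cache$dh
  scale <- cache$scale
  dQ <- matrix(0, nrow(dout), ncol(dout))
  dK <- dQ[0, , drop = FALSE]  # placeholder; rebuilt below
  n_k <- nrow(cache$heads[[1]]$Kh)
  dK <- matrix(0, n_k, ncol(dout))
  dV <- matrix(0, n_k, ncol(dout))
  for (j in seq_len(h)) {
    colsj <- ((j - 1) * dh + 1):(j * dh)
    hc <- cache$heads[[j]]
    dOh <- dout[, colsj, drop = FALSE]
    dP <- tcrossprod(dOh, hc$Vh)
    dVh <- crossprod(hc$P, dOh)
    dS <- softmax_rows_bwd(dP, hc$P)
    dQ[, colsj] <- (dS %*% hc$Kh) * scale
    dK[, colsj] <- (crossprod(dS, hc$Qh)) * scale
    dV[, colsj] <- dVh
  }
  list(dQ = dQ, dK = dK, dV = dV)
}

#' Fuse per-window context outputs
#'
#' Unweighted arithmetic mean of the `F` window context vectors, optionally
#' followed by layer normalization (`ln = list(g, b)`).
#'
#' @param ctx `F x N` matrix of window context outputs (or list of vectors).
#' @param ln Optional layer-norm parameters `list(g, b)`.
#' @return List with `fused` (length-`N` vector), `pre_norm`, and `cache`.
#' @export
fuse_windows <- function(ctx, ln = NULL) {
  if (is.list(ctx) && !is.matrix(ctx)) ctx <- do.call(rbind, ctx)
  assert_that(nrow(ctx) >= 1, "empty window list")
  pre <- colMeans(ctx)
  if (is.null(ln)) {
    return(list(fused = pre, pre_norm = pre, cache = NULL))
  }
  lnf <- layernorm_fwd(matrix(pre, 1), ln$g, ln$b)
  list(fused = as.numeric(lnf$out), pre_norm = pre, cache = lnf)
}

# --- full FWAM stack ------------------------------------------------------

# One transformer block: pre-norm windowed attention with per-window context
# tokens, residual scatter-average back onto the sequence, then a pre-norm
# ReLU feed-forward.
fwam_block_fwd <- function(X, Ctx, bp, spec, cfg, keep_cache = FALSE) {
  ln_x <- layernorm_fwd(X, bp$ln1_g, bp$ln1_b)
  ln_c <- layernorm_fwd(Ctx, bp$ln1_g, bp$ln1_b)
  Xn <- ln_x$out; Cn <- ln_c$out
  Fh <- spec$F
  N <- ncol(X)
  acc <- matrix(0, spec$T, N)
  count <- integer(spec$T)
  dctx <- matrix(0, Fh, N)
  wcaches <- if (keep_cache) vector("list", Fh) else NULL
  for (i in seq_len(Fh)) {
    idx <- window_indices(spec, i)
    q_in <- rbind(Cn[i, , drop = FALSE], Xn[idx$base, , drop = FALSE])
    k_in <- rbind(Cn[i, , drop = FALSE],
                  Xn[idx$left, , drop = FALSE],
                  Xn[idx$base, , drop = FALSE],
                  Xn[idx$right, , drop = FALSE])
    Q <- col_add(q_in %*% t(bp$Wq), bp$bq)
    K <- col_add(k_in %*% t(bp$Wk), bp$bk)
    att <- window_attention(Q, K, K, cfg, keep_cache = keep_cache)
    O <- col_add(att$out %*% t(bp$Wo), bp$bo)
    dctx[i, ] <- O[1, ]
    acc[idx$base, ] <- acc[idx$base, , drop = FALSE] + O[-1, , drop = FALSE]
    count[idx$base] <- count[idx$base] + 1L
    if (keep_cache) {
      wcaches[[i]] <- list(idx = idx, q_in = q_in, k_in = k_in,
                           att_cache = att$cache, att_out = att$out)
    }
  }
  wts <- 1 / pmax(count, 1L)
  X1 <- X + acc * wts
  C1 <- Ctx + dctx
  # feed-forward (pre-norm, residual)
  ff_fwd <- function(U) {
    lnu <- layernorm_fwd(U, bp$ln2_g, bp$ln2_b)
    h1 <- col_add(lnu$out %*% t(bp$Wf1), bp$bf1)
    r <- relu_fwd(h1)
    h2 <- col_add(r$out %*% t(bp$Wf2), bp$bf2)
    list(out = U + h2, cache = list(lnu = lnu, relu = r))
  }
  if (cfg$ff_tokens == "all") {
    fx <- ff_fwd(X1); X2 <- fx$out
  } else {
    fx <- NULL; X2 <- X1
  }
  fc <- ff_fwd(C1); C2 <- fc$out
  cache <- if (keep_cache) {
    list(ln_x = ln_x, ln_c = ln_c, wcaches = wcaches, wts = wts,
         ff_x = fx, ff_c = fc, X1 = X1, C1 = C1)
  } else NULL
  list(X = X2, Ctx = C2, cache = cache)
}

fwam_block_bwd <- function(dX2, dC2, cache, bp, spec, cfg) {
  g <- list(Wq = 0, bq = 0, Wk = 0, bk = 0, Wo = 0, bo = 0,
            ln1_g = 0, ln1_b = 0, ln2_g = 0, ln2_b = 0,
            Wf1 = 0, bf1 = 0, Wf2 = 0, bf2 = 0)
  ff_bwd <- function(dout, fcache) {
    dh2 <- dout
    dWf2 <- crossprod(dh2, fcache$relu$out)
    dbf2 <- colSums(dh2)
    dr <- dh2 %*% bp$Wf2
    dh1 <- relu_bwd(dr, fcache$relu)
    dWf1 <- crossprod(dh1, fcache$lnu$out)
    dbf1 <- colSums(dh1)
    dln <- dh1 %*% bp$Wf1
    lb <- layernorm_bwd(dln, fcache$lnu, bp$ln2_g)
    list(dU = dout + lb$dx, dWf1 = dWf1, dbf1 = dbf1, dWf2 = dWf2,
         dbf2 = dbf2, dg = lb$dgamma, db = lb$dbeta)
  }
  if (cfg$ff_tokens == "all") {
    fb <- ff_bwd(dX2, cache$ff_x$cache)
    dX1 <- fb$dU
    g$Wf1 <- g$Wf1 + fb$dWf1; g$bf1 <- g$bf1 + fb$dbf1
    g$Wf2 <- g$Wf2 + fb$dWf2; g$bf2 <- g$bf2 + fb$dbf2
    g$ln2_g <- g$ln2_g + fb$dg; g$ln2_b <- g$ln2_b + fb$db
  } else {
    dX1 <- dX2
  }
  fbc <- ff_bwd(dC2, cache$ff_c$cache)
  dC1 <- fbc$dU
  g$Wf1 <- g$Wf1 + fbc$dWf1; g$bf1 <- g$bf1 + fbc$dbf1
  g$Wf2 <- g$Wf2 + fbc$dWf2; g$bf2 <- g$bf2 + fbc$dbf2
  g$ln2_g <- g$ln2_g + fbc$dg; g$ln2_b <- g$ln2_b + fbc$db

  # residual: dX flows straight through plus via the attention branch
  dX <- dX1
  dCtx <- dC1
  dXn <- matrix(0, nrow(dX1), ncol(dX1))
  dCn <- matrix(0, nrow(dC1), ncol(dC1))
  for (i in seq_len(spec$F)) {
    wc <- cache$wcaches[[i]]
    idx <- wc$idx
    dO <- rbind(dC1[i, , drop = FALSE],
                dX1[idx$base, , drop = FALSE] * cache$wts[idx$base])
    dAtt <- dO %*% bp$Wo
    g$Wo <- g$Wo + crossprod(dO, wc$att_out)
    g$bo <- g$bo + colSums(dO)
    ab <- window_attention_bwd(dAtt, wc$att_cache, cfg)
    dK_total <- ab$dK + ab$dV  # V is K
    dq_in <- ab$dQ %*% bp$Wq
    dk_in <- dK_total %*% bp$Wk
    g$Wq <- g$Wq + crossprod(ab$dQ, wc$q_in)
    g$bq <- g$bq + colSums(ab$dQ)
    g$Wk <- g$Wk + crossprod(dK_total, wc$k_in)
    g$bk <- g$bk + colSums(dK_total)
    # scatter gradients back to normalized sequence/context rows
    dCn[i, ] <- dCn[i, ] + dq_in[1, ] + dk_in[1, ]
    b_rows <- dq_in[-1, , drop = FALSE]
    W <- spec$W; L <- length(idx$left)
    k_base <- dk_in[(1 + L + 1):(1 + L + W), , drop = FALSE]
    for (r in seq_along(idx$base)) {
      p <- idx$base[r]
      dXn[p, ] <- dXn[p, ] + b_rows[r, ] + k_base[r, ]
    }
    if (L > 0) {
      k_left <- dk_in[2:(1 + L), , drop = FALSE]
      k_right <- dk_in[(1 + L + W + 1):(1 + L + W + L), , drop = FALSE]
      for (r in seq_len(L)) {
        dXn[idx$left[r], ] <- dXn[idx$left[r], ] + k_left[r, ]
        dXn[idx$right[r], ] <- dXn[idx$right[r], ] + k_right[r, ]
      }
    }
  }
  lbx <- layernorm_bwd(dXn, cache$ln_x, bp$ln1_g)
  lbc <- layernorm_bwd(dCn, cache$ln_c, bp$ln1_g)
  g$ln1_g <- g$ln1_g + lbx$dgamma + lbc$dgamma
  g$ln1_b <- g$ln1_b + lbx$dbeta + lbc$dbeta
  dX <- dX + lbx$dx
  dCtx <- dCtx + lbc$dx
  list(dX = dX, dCtx = dCtx, grads = g)
}

#' Forward pass of the fused window attention stack
#'
#' `depth` transformer blocks of windowed multi-head attention with
#' per-window context/auxiliary tokens (initialized from one shared learnable
#' vector), residual connections and feed-forward layers; the final fused
#' feature is the arithmetic mean of the window context tokens followed by
#' layer normalization.
#'
#' @param tokens `T x N` token matrix.
#' @param params Parameters from `init_fwam_params`.
#' @param spec A [window_spec()].
#' @param cfg An [attention_config()].
#' @param keep_cache Retain intermediates for the backward pass.
#' @return List with `fused` (length-`N`), `pre_norm`, per-window `ctx`, and
#'   `cache`.
#' @export
fwam_forward <- function(tokens, params, spec = window_spec(),
                         cfg = attention_config(), keep_cache = FALSE) {
  N <- cfg$feature_dim
  assert_that(ncol(tokens) == N, "token feature dimension mismatch")
  X <- tokens
  Ctx <- matrix(params$ctx0, spec$F, N, byrow = TRUE)
  bcaches <- if (keep_cache) vector("list", cfg$depth) else NULL
  for (b in seq_len(cfg$depth)) {
    blk <- fwam_block_fwd(X, Ctx, params$blocks[[b]], spec, cfg, keep_cache)
    X <- blk$X; Ctx <- blk$Ctx
    if (keep_cache) bcaches[[b]] <- blk$cache
  }
  fo <- fuse_windows(Ctx, ln = list(g = params$lnf_g, b = params$lnf_b))
  list(fused = fo$fused, pre_norm = fo$pre_norm, ctx = Ctx,
       cache = list(blocks = bcaches, fuse = fo$cache, F = spec$F))
}

fwam_backward <- function(dfused, cache, params, spec, cfg) {
  lb <- layernorm_bwd(matrix(dfused, 1), cache$fuse, params$lnf_g)
  dpre <- as.numeric(lb$dx)
  Fh <- spec$F
  dCtx <- matrix(dpre / Fh, Fh, length(dpre), byrow = TRUE)
  dX <- matrix(0, spec$T, cfg$feature_dim)
  gblocks <- vector("list", cfg$depth)
  for (b in rev(seq_len(cfg$depth))) {
    bb <- fwam_block_bwd(dX, dCtx, cache$blocks[[b]], params$blocks[[b]],
                         spec, cfg)
    dX <- bb$dX; dCtx <- bb$dCtx
    gblocks[[b]] <- bb$grads
  }
  list(dtokens = dX,
       grads = list(blocks = gblocks,
                    ctx0 = colSums(dCtx),
                    lnf_g = as.numeric(lb$dgamma),
                    lnf_b = as.numeric(lb$dbeta)))
}
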