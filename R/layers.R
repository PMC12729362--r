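# Differentiable layer primitives. Each *_fwd returns the output plus the
# cache its paired *_bwd needs; backward functions return gradients w.r.t.
# inputs and parameters. Feature maps are (n_vox x C) matrices; token
# matrices are (rows x features). Per-column scale/shift uses rep() rather
# than sweep(): the feature maps run to millions of elements and sweep's
# aperm path dominates runtime otherwise.

EPS_NORM <- 1e-5

# x + v / x * v broadcast over columns (length(v) == ncol(x))
col_add <- function(x, v) x + rep(v, each = nrow(x))
col_mul <- function(x, v) x * rep(v, each = nrow(x))

relu_fwd <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  out <- cpp_relu(x)
  list(out = out)
}
relu_bwd <- function(dout, cache) cpp_relu_bwd(dout, cache$out)

# Row-wise layer normalization with learnable gain/shift (length = ncol).
# Row statistics recycle naturally over columns in column-major arithmetic.
layernorm_fwd <- function(x, gamma, beta) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + EPS_NORM)
  xhat <- xc * inv
  out <- col_add(col_mul(xhat, gamma), beta)
  list(out = out, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dout, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- col_mul(dout, gamma)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Per-sample (instance) normalization of a conv feature map: each channel
# (column) is standardized over its spatial/phase positions, then scaled and
# shifted. Fills the normalize-scale-shift role of batch normalization while
# keeping single-sample processing deterministic.
instnorm_fwd <- function(x, gamma, beta) {
  cpp_instnorm_fwd(x, gamma, beta, EPS_NORM)
}

instnorm_bwd <- function(dout, cache, gamma) {
  cpp_instnorm_bwd(dout, cache$xc, cache$inv, gamma)
}

# y = x %*% t(W) + b with W (out x in), x (n x in).
linear_fwd <- function(x, W, b) {
  out <- col_add(x %*% t(W), b)
  list(out = out, x = x)
}

linear_bwd <- function(dout, cache, W) {
  list(dx = dout %*% W,
       dW = crossprod(dout, cache$x),
       db = colSums(dout))
}

softmax_rows <- function(x) {
  m <- x[max.col(x, ties.method = "first") * nrow(x) - nrow(x) + seq_len(nrow(x))]
  e <- exp(x - m)
  e / rowSums(e)
}

softmax_rows_bwd <- function(dp, p) {
  p * (dp - rowSums(dp * p))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Fan-in scaled Gaussian initialization.
init_weight <- function(n_out, n_in, fan_in = n_in) {
  matrix(rnorm(n_out * n_in, 0, sqrt(2 / fan_in)), n_out, n_in)
}
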