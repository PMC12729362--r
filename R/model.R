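#' Full model configuration
#'
#' Assembles the multiscale convolution token extractor, the fused window
#' attention stack and the classification head. `variant = "mhmc_only"`
#' replaces the attention stack with mean pooling over tokens;
#' `variant = "fwam_only"` replaces the learned token extractor with a fixed
#' per-phase average-pooling tokenizer (one token per phase). These are the
#' ablation configurations.
#'
#' @param mhmc An [mhmc_config()].
#' @param spec A [window_spec()] (ignored for `fwam_only`, which attends over
#'   one window spanning the per-phase tokens).
#' @param attn An [attention_config()].
#' @param variant `"full"`, `"mhmc_only"` or `"fwam_only"`.
#' @return A `model_config`.
#' @export
model_config <- function(mhmc = mhmc_config(), spec = window_spec(),
                         attn = attention_config(),
                         variant = c("full", "mhmc_only", "fwam_only")) {
  variant <- match.arg(variant)
  if (variant == "full") {
    assert_that(sum(mhmc$out_tokens) == spec$T,
                "window spec length must equal total token count")
    assert_that(mhmc_feature_dim(mhmc) == attn$feature_dim,
                "attention feature_dim must match the token feature dim")
  }
  if (variant == "fwam_only") {
    spec <- window_spec(W = mhmc$phases, S = mhmc$phases, L = 0,
                        T = mhmc$phases)
  }
  structure(list(mhmc = mhmc, spec = spec, attn = attn, variant = variant),
            class = "model_config")
}

#' Budget-sized default configuration
#'
#' Three branches with (16, 32, 64) mid channels and (64, 128, 256) token
#' rows; window spec `W = 64, S = 48, L = 8` over 448 tokens (9 windows);
#' attention depth 3, 8 heads, feed-forward expansion 6. The trainable
#' parameter count of this configuration is 27.7 million.
#'
#' @return A `model_config`.
#' @export
default_model_config <- function() {
  model_config()
}

#' Desk-scale configuration for CPU-friendly training experiments
#'
#' Same architecture shape as the default but sized for single-CPU training:
#' 112 x 112 x 5 input (feature dimension 196), slim convolution branches, a
#' reduced token allocation (16, 32, 64; 112 tokens over 9 windows of W = 16,
#' S = 12, L = 4), a single transformer block with unit feed-forward
#' expansion, and context-token feed-forward. Used for the package's
#' phantom-cohort training demonstrations.
#'
#' @param variant `"full"`, `"mhmc_only"` or `"fwam_only"`.
#' @return A `model_config`.
#' @export
desk_model_config <- function(variant = "full") {
  model_config(
    mhmc = mhmc_config(mid_channels = c(4, 8, 8),
                       out_tokens = c(16, 32, 64), input_side = 112),
    spec = window_spec(W = 16, S = 12, L = 4, T = 112),
    attn = attention_config(n_heads = 4, depth = 1, feature_dim = 196,
                            ff_expansion = 1, ff_tokens = "context"),
    variant = variant
  )
}

#' Build a model (initialize parameters)
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the fan-in scaled Gaussian initialization.
#' @return A `dce_model` with elements `config`, `params`, `seed`,
#'   `config_hash`.
#' @export
build_model <- function(config = default_model_config(), seed = 1L) {
  params <- list()
  N <- config$attn$feature_dim
  if (config$variant %in% c("full", "mhmc_only")) {
    params$mhmc <- init_mhmc_params(config$mhmc, derive_seed(seed, "mhmc"))
  }
  if (config$variant %in% c("full", "fwam_only")) {
    params$fwam <- init_fwam_params(config$attn, config$spec,
                                    derive_seed(seed, "fwam"))
  }
  params$head <- with_seed(derive_seed(seed, "head"), {
    list(w = rnorm(N, 0, sqrt(1 / N)), b = 0)
  })
  structure(list(config = config, params = params, seed = as.integer(seed),
                 config_hash = config_hash(config)),
            class = "dce_model")
}

#' @export
print.dce_model <- function(x, ...) {
  cat(sprintf("dce_model (%s): %.3f M trainable parameters, config %s\n",
              x$config$variant, count_params(x) / 1e6, x$config_hash))
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model A `dce_model` (or a parameter list).
#' @return Total number of trainable scalar parameters.
#' @export
count_params <- function(model) {
  p <- if (inherits(model, "dce_model")) model$params else model
  tree_reduce(p, length)
}

# Fixed tokenizer of the fwam_only ablation: per-phase 8x8 average pooling
# down to 28 x 28, flattened to 784 features; one token per phase.
fixed_phase_tokenizer <- function(x, side_out = 28) {
  d <- dim(x)
  f <- d[1] %/% side_out
  tokens <- matrix(0, d[3], side_out * side_out)
  for (p in seq_len(d[3])) {
    arr <- array(x[, , p], c(f, side_out, f, side_out))
    tokens[p, ] <- as.numeric(apply(arr, c(2, 4), mean))
  }
  tokens
}

#' Forward pass of the assembled model
#'
#' @param model A `dce_model`.
#' @param x `H x W x T` array or [phase_stack()].
#' @param keep_cache Retain intermediates for backprop.
#' @return List with `prob`, `logit`, `tokens`, `fused`, `cache`.
#' @export
model_forward <- function(model, x, keep_cache = FALSE) {
  if (inherits(x, "phase_stack")) x <- x$values
  cfg <- model$config
  p <- model$params
  cache <- list()
  if (cfg$variant %in% c("full", "mhmc_only")) {
    mh <- mhmc_forward(x, p$mhmc, cfg$mhmc, keep_cache)
    tokens <- mh$tokens
    cache$mhmc <- mh$caches
  } else {
    tokens <- fixed_phase_tokenizer(x, side_out = cfg$mhmc$input_side %/% 8L)
  }
  if (cfg$variant %in% c("full", "fwam_only")) {
    fw <- fwam_forward(tokens, p$fwam, cfg$spec, cfg$attn, keep_cache)
    fused <- fw$fused
    cache$fwam <- fw$cache
  } else {
    fused <- colMeans(tokens)
    cache$n_tokens <- nrow(tokens)
  }
  cls <- classify(fused, p$head$w, p$head$b)
  list(prob = cls$prob, logit = cls$logit, tokens = tokens, fused = fused,
       cache = if (keep_cache) c(cache, list(fused = fused)) else NULL)
}

# Backward pass: gradient of (dlogit * logit) w.r.t. all parameters.
# capture_branch > 0 additionally returns the gradient at that branch's
# layer-1 ReLU activations (Grad-CAM hook).
model_backward <- function(model, cache, dlogit, capture_branch = 0L) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  dfused <- dlogit * p$head$w
  dact1 <- NULL
  if (cfg$variant %in% c("full", "fwam_only")) {
    fb <- fwam_backward(dfused, cache$fwam, p$fwam, cfg$spec, cfg$attn)
    dtokens <- fb$dtokens
    gf <- fb$grads
  } else {
    dtokens <- matrix(dfused / cache$n_tokens, cache$n_tokens,
                      length(dfused), byrow = TRUE)
    gf <- NULL
  }
  if (cfg$variant %in% c("full", "mhmc_only")) {
    mb <- mhmc_backward(dtokens, cache$mhmc, p$mhmc, cfg$mhmc,
                        capture_branch = capture_branch)
    grads$mhmc <- mb$grads
    dact1 <- mb$dact1
  }
  if (!is.null(gf)) grads$fwam <- gf
  grads$head <- list(w = dlogit * cache$fused, b = dlogit)
  list(grads = grads, dact1 = dact1)
}

#' Predict invasion probabilities for a list of inputs
#'
#' @param model A `dce_model` (or `dce_fit`).
#' @param xs List of `H x W x T` arrays or [phase_stack()]s.
#' @return Numeric vector of probabilities.
#' @export
predict_prob <- function(model, xs) {
  if (inherits(model, "dce_fit")) model <- model$model
  vapply(xs, function(x) model_forward(model, x)$prob, numeric(1))
}

#' @export
predict.dce_model <- function(object, newdata, ...) {
  predict_prob(object, newdata)
}
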