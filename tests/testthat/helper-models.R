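# Shared fixtures: a miniature model configuration (16 x 16 x 5 input,
# 9 tokens of 4 features) for fast exact checks, and a finite-difference
# gradient checker over the nested parameter tree.

tiny_model_config <- function(variant = "full", depth = 1,
                              ff_tokens = "all", raw_di_scaling = FALSE) {
  model_config(
    mhmc = mhmc_config(kernels = c(1, 3, 5), mid_channels = c(2, 3, 3),
                       out_tokens = c(2, 3, 4), input_side = 16),
    spec = window_spec(W = 3, S = 3, L = 1, T = 9),
    attn = attention_config(n_heads = 2, depth = depth, feature_dim = 4,
                            ff_expansion = 2, ff_tokens = ff_tokens,
                            raw_di_scaling = raw_di_scaling),
    variant = variant
  )
}

tiny_input <- function(seed = 1) {
  windmri:::with_seed(seed, array(rnorm(16 * 16 * 5), c(16, 16, 5)))
}

# Numeric vs analytic gradient on a sample of coordinates of every leaf.
# Returns the worst relative discrepancy observed.
check_gradients <- function(model, x, y, n_coords = 3, h = 1e-5, seed = 42) {
  fw <- model_forward(model, x, keep_cache = TRUE)
  dlogit <- fw$prob - y  # d(bce)/d(logit) for a single sample
  grads <- windmri:::model_backward(model, fw$cache, dlogit)$grads

  loss_at <- function(params) {
    m <- model; m$params <- params
    bce_loss(model_forward(m, x)$prob, y)
  }

  flat_paths <- function(tree, prefix = character()) {
    if (is.list(tree)) {
      unlist(lapply(names(tree) %||% seq_along(tree), function(nm) {
        flat_paths(tree[[nm]], c(prefix, nm))
      }), recursive = FALSE)
    } else {
      list(prefix)
    }
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  get_leaf <- function(tree, path) {
    for (p in path) tree <- tree[[p]]
    tree
  }
  set_leaf <- function(tree, path, value) {
    if (length(path) == 1) {
      tree[[path]] <- value
      return(tree)
    }
    tree[[path[1]]] <- set_leaf(tree[[path[1]]], path[-1], value)
    tree
  }

  paths <- flat_paths(model$params)
  worst <- 0
  set.seed(seed)
  for (path in paths) {
    leaf <- get_leaf(model$params, path)
    g_leaf <- get_leaf(grads, path)
    ncheck <- min(n_coords, length(leaf))
    for (ix in sample(length(leaf), ncheck)) {
      pp <- model$params
      l1 <- leaf; l1[ix] <- l1[ix] + h
      fp <- loss_at(set_leaf(pp, path, l1))
      l2 <- leaf; l2[ix] <- l2[ix] - h
      fm <- loss_at(set_leaf(pp, path, l2))
      num <- (fp - fm) / (2 * h)
      ana <- g_leaf[ix]
      denom <- max(abs(num), abs(ana), 1e-6)
      worst <- max(worst, abs(num - ana) / denom)
    }
  }
  worst
}

# Small phantom cohort cached across tests within one run.
shared_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(phantom_config(n_patients = 24, seed = 11))
    }
    cache
  }
})
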