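#' @useDynLib windmri, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd quantile pnorm var
#' @importFrom utils head tail combn write.csv
#' @importFrom rlang abort .data `%||%`
#' @keywords internal
"_PACKAGE"

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All package randomness funnels through this.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stream label, staying within
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483562) + 1L
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) rlang::abort(msg)
  invisible(TRUE)
}

# Apply `f` to every numeric leaf of a nested list, preserving structure.
tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, tree_map, f = f) else f(x)
}

# Combine two structurally identical nested lists leaf-wise.
tree_map2 <- function(x, y, f) {
  if (is.list(x)) {
    out <- mapply(tree_map2, x, y, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    out
  } else {
    f(x, y)
  }
}

# Sum of a function applied over all leaves (e.g. parameter counting).
tree_reduce <- function(x, f, acc = 0) {
  if (is.list(x)) {
    for (el in x) acc <- tree_reduce(el, f, acc)
    acc
  } else {
    acc + f(x)
  }
}

# Flatten all numeric leaves into one vector (finite-difference checks).
tree_flatten <- function(x) {
  if (is.list(x)) unlist(lapply(x, tree_flatten), use.names = FALSE) else as.numeric(x)
}

# Short stable fingerprint of an R object (config hashes on artifacts).
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  # 32-bit FNV-1a over the serialized payload
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
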