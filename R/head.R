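#' Classification head: invasion probability from the fused feature
#'
#' Affine projection of the fused feature followed by the logistic function:
#' `y_p = sigmoid(w . F_o + b)`. The predicted label uses a 0.5 threshold.
#'
#' @param fused Length-`N` fused feature vector.
#' @param w Length-`N` weight vector.
#' @param b Scalar bias.
#' @return List with `prob`, `logit`, `label_hat`.
#' @export
classify <- function(fused, w, b) {
  logit <- sum(fused * w) + b
  prob <- sigmoid(logit)
  list(prob = prob, logit = logit, label_hat = as.integer(prob >= 0.5))
}

#' Mean binary cross-entropy loss
#'
#' `-(1/N) sum[y log y_p + (1 - y) log(1 - y_p)]`, with probabilities clamped
#' to `[eps, 1 - eps]` inside the logarithms (the loss is undefined at exact
#' 0/1).
#'
#' @param probs Predicted probabilities in `[0, 1]`.
#' @param labels Ground-truth labels in `{0, 1}`.
#' @param eps Clamp width.
#' @return Scalar loss (nonnegative).
#' @export
bce_loss <- function(probs, labels, eps = 1e-7) {
  assert_that(length(probs) == length(labels), "length mismatch")
  assert_that(length(probs) > 0, "empty batch")
  assert_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  p <- pmin(pmax(probs, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# d(loss)/d(logit) for sigmoid + mean BCE: (p - y)/N per sample.
bce_logit_grad <- function(probs, labels) {
  (probs - labels) / length(probs)
}
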