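# AdamW optimizer over a nested parameter tree.

adamw_init <- function(params) {
  list(m = tree_map(params, function(x) x * 0),
       v = tree_map(params, function(x) x * 0),
       t = 0L)
}

adamw_step <- function(params, grads, state, lr = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 0.01) {
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v, function(m, v) {
    (m / bc1) / (sqrt(v / bc2) + eps)
  })
  params <- tree_map2(params, upd, function(p, u) p - lr * u)
  if (weight_decay > 0) {
    params <- tree_map(params, function(p) p * (1 - lr * weight_decay))
  }
  list(params = params, state = state)
}

grad_global_norm <- function(grads) {
  sqrt(tree_reduce(grads, function(g) sum(g^2)))
}

scale_grads <- function(grads, s) tree_map(grads, function(g) g * s)

#' Train a model on preprocessed samples
#'
#' Minimizes mean binary cross-entropy end-to-end (token extractor, attention
#' stack and head jointly) with AdamW, per-epoch shuffling, optional minority
#' oversampling and early stopping on validation loss. The non-invasive class
#' is the negative class (label 0). Fully seeded: identical seeds give
#' identical loss curves.
#'
#' @param model A `dce_model` from [build_model()].
#' @param x_train,x_val Lists of `H x W x T` arrays or [phase_stack()]s.
#' @param y_train,y_val Binary labels (1 = invasive).
#' @param epochs Maximum epochs.
#' @param batch_size Gradient-accumulation batch size.
#' @param lr AdamW learning rate.
#' @param weight_decay AdamW decoupled weight decay.
#' @param patience Early-stopping patience on validation loss.
#' @param clip Global gradient-norm clip (0 disables).
#' @param oversample Oversample the minority class each epoch.
#' @param augment Optional [augment_policy()]; when supplied, every training
#'   sample (including oversampled duplicates, which thereby receive
#'   independent jitter) is augmented with a seed derived from the epoch and
#'   position.
#' @param select_on Checkpoint selection criterion: validation `"loss"` or
#'   `"auc"`.
#' @param seed Integer seed controlling shuffling/oversampling/augmentation.
#' @param verbose Print per-epoch progress.
#' @return A `dce_fit`: `model` (best-validation parameters), `history`
#'   tibble (epoch, train_loss, val_loss, val_auc), `best_epoch`.
#' @export
train_model <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                        epochs = 30, batch_size = 8, lr = 1e-4,
                        weight_decay = 0.01, patience = 10, clip = 5,
                        oversample = TRUE, augment = NULL,
                        select_on = c("loss", "auc"),
                        seed = 1L, verbose = FALSE) {
  select_on <- match.arg(select_on)
  assert_that(length(x_train) == length(y_train) && length(y_train) > 0,
              "non-empty matching training data required")
  has_val <- !is.null(x_val) && length(x_val) > 0
  params <- model$params
  state <- adamw_init(params)
  history <- vector("list", epochs)
  best_val <- Inf; best_params <- params; best_epoch <- 0L; wait <- 0L

  eval_split <- function(params, xs, ys) {
    m <- model; m$params <- params
    probs <- vapply(xs, function(x) model_forward(m, x)$prob, numeric(1))
    list(loss = bce_loss(probs, ys),
         auc = if (length(unique(ys)) > 1) roc_auc(probs, ys)$auc else NA_real_)
  }

  for (ep in seq_len(epochs)) {
    idx <- with_seed(derive_seed(seed, paste0("epoch", ep)), {
      ix <- seq_along(x_train)
      if (oversample) {
        n1 <- sum(y_train == 1); n0 <- sum(y_train == 0)
        if (n1 != n0 && n1 > 0 && n0 > 0) {
          minority <- if (n1 < n0) which(y_train == 1) else which(y_train == 0)
          extra <- sample(minority, abs(n0 - n1), replace = TRUE)
          ix <- c(ix, extra)
        }
      }
      sample(ix)
    })
    losses <- numeric(0)
    b0 <- 1
    while (b0 <= length(idx)) {
      batch <- idx[b0:min(b0 + batch_size - 1, length(idx))]
      b0 <- b0 + batch_size
      acc <- NULL
      bl <- numeric(length(batch))
      for (j in seq_along(batch)) {
        i <- batch[j]
        m <- model; m$params <- params
        xi <- x_train[[i]]
        if (!is.null(augment)) {
          st <- if (inherits(xi, "phase_stack")) xi else phase_stack(xi, normalized = TRUE)
          xi <- windmri::augment(st, augment,
                                 seed = derive_seed(seed, sprintf("aug%d_%d_%d", ep, b0, j)))
        }
        fw <- model_forward(m, xi, keep_cache = TRUE)
        bl[j] <- bce_loss(fw$prob, y_train[i])
        dlogit <- (fw$prob - y_train[i]) / length(batch)
        g <- model_backward(m, fw$cache, dlogit)$grads
        acc <- if (is.null(acc)) g else tree_map2(acc, g, `+`)
      }
      if (!all(is.finite(bl))) {
        rlang::abort(sprintf("training diverged (non-finite loss) at epoch %d", ep))
      }
      if (clip > 0) {
        gn <- grad_global_norm(acc)
        if (is.finite(gn) && gn > clip) acc <- scale_grads(acc, clip / gn)
      }
      st <- adamw_step(params, acc, state, lr = lr, weight_decay = weight_decay)
      params <- st$params; state <- st$state
      losses <- c(losses, mean(bl))
    }
    tr_loss <- mean(losses)
    if (has_val) {
      ev <- eval_split(params, x_val, y_val)
      history[[ep]] <- tibble::tibble(epoch = ep, train_loss = tr_loss,
                                      val_loss = ev$loss, val_auc = ev$auc)
      if (verbose) {
        message(sprintf("epoch %d: train %.4f val %.4f auc %.3f",
                        ep, tr_loss, ev$loss, ev$auc))
      }
      crit <- if (select_on == "auc" && is.finite(ev$auc)) -ev$auc else ev$loss
      if (crit < best_val - 1e-6) {
        best_val <- crit; best_params <- params
        best_epoch <- ep; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) {
          history <- history[seq_len(ep)]
          break
        }
      }
    } else {
      history[[ep]] <- tibble::tibble(epoch = ep, train_loss = tr_loss,
                                      val_loss = NA_real_, val_auc = NA_real_)
      best_params <- params; best_epoch <- ep
      if (verbose) message(sprintf("epoch %d: train %.4f", ep, tr_loss))
    }
  }
  fitted <- model
  fitted$params <- best_params
  structure(list(model = fitted,
                 history = dplyr::bind_rows(history[!vapply(history, is.null, TRUE)]),
                 best_epoch = best_epoch,
                 config_hash = model$config_hash),
            class = "dce_fit")
}

#' @export
print.dce_fit <- function(x, ...) {
  cat(sprintf("dce_fit: %d epochs (best %d), final train loss %.4f\n",
              nrow(x$history), x$best_epoch,
              x$history$train_loss[nrow(x$history)]))
  invisible(x)
}

#' @export
predict.dce_fit <- function(object, newdata, ...) {
  predict_prob(object$model, newdata)
}

#' Tidy the training history of a fit
#'
#' @param x A `dce_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch.
#' @method tidy dce_fit
#' @export
tidy.dce_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x A `dce_fit`.
#' @param ... Unused.
#' @return Tibble with best epoch, best validation loss/AUC and parameter count.
#' @method glance dce_fit
#' @export
glance.dce_fit <- function(x, ...) {
  h <- x$history
  best <- if (x$best_epoch > 0 && x$best_epoch <= nrow(h)) h[x$best_epoch, ] else h[nrow(h), ]
  tibble::tibble(epochs = nrow(h), best_epoch = x$best_epoch,
                 val_loss = best$val_loss, val_auc = best$val_auc,
                 n_params = count_params(x$model))
}

#' Plot a training loss curve
#'
#' @param object A `dce_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dce_fit
#' @export
autoplot.dce_fit <- function(object, ...) {
  h <- object$history
  df <- dplyr::bind_rows(
    tibble::tibble(epoch = h$epoch, loss = h$train_loss, split = "train"),
    tibble::tibble(epoch = h$epoch, loss = h$val_loss, split = "validation")
  )
  df <- df[is.finite(df$loss), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}
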