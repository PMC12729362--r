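#' Pipeline configuration
#'
#' Nested configuration for the end-to-end run: phantom simulation, cohort
#' split, preprocessing, model, training, evaluation and saliency export.
#' Every default is recorded in the returned object, and a short config hash
#' is stamped into all artifacts so outputs from different configurations
#' cannot be mixed silently.
#'
#' @param phantom A [phantom_config()].
#' @param split Either `list(ratio = c(6, 1, 3)/10)` or
#'   `list(counts = c(train, val, test))`.
#' @param model A [model_config()]; desk-scale by default so the pipeline
#'   runs in CPU-minutes.
#' @param train List of [train_model()] arguments.
#' @param eval List with `threshold` and bootstrap `B`.
#' @param explain List with `n_examples` saliency panels to export.
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Output directory (NULL = no files written).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(n_patients = 60),
                            split = list(ratio = c(6, 1, 3) / 10),
                            model = desk_model_config(),
                            train = list(epochs = 4, batch_size = 8,
                                         lr = 1e-3, patience = 4),
                            eval = list(threshold = 0.5, B = 500),
                            explain = list(n_examples = 1),
                            seed = 1L, out_dir = NULL) {
  structure(list(phantom = phantom, split = split, model = model,
                 train = train, eval = eval, explain = explain,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full pipeline: simulate, preprocess, train, evaluate, explain
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return List with `cohort`, `split`, `stats`, `fit`, `report` (an
#'   `eval_report`), `scores` tibble, `saliency`, and `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  hash <- config_hash(config)
  say <- function(...) if (verbose) message(sprintf(...))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  say("[simulate] %d patients", config$phantom$n_patients)
  cohort <- simulate_cohort(config$phantom)

  say("[split]")
  split <- split_cohort(cohort$manifest$patient_id, cohort$manifest$label,
                        ratio = config$split$ratio %||% c(6, 1, 3) / 10,
                        counts = config$split$counts,
                        seed = derive_seed(config$seed, "split"))
  by_id <- stats::setNames(cohort$samples, cohort$manifest$patient_id)
  tr <- by_id[split$train_ids]; va <- by_id[split$val_ids]
  te <- by_id[split$test_ids]

  say("[normalize] fitting stats on %d training samples", length(tr))
  stats <- fit_norm_stats(lapply(tr, function(s) s$phases),
                          lapply(tr, function(s) s$tumor_mask),
                          ids = names(tr))
  prep <- function(ss) lapply(ss, preprocess_sample, stats = stats,
                              target_side = config$model$mhmc$input_side)
  x_tr <- prep(tr); x_va <- prep(va); x_te <- prep(te)
  y_tr <- vapply(tr, `[[`, 0L, "label")
  y_va <- vapply(va, `[[`, 0L, "label")
  y_te <- vapply(te, `[[`, 0L, "label")

  say("[train] %s variant", config$model$variant)
  model <- build_model(config$model, seed = derive_seed(config$seed, "init"))
  fit <- do.call(train_model, c(
    list(model = model, x_train = x_tr, y_train = y_tr,
         x_val = x_va, y_val = y_va,
         seed = derive_seed(config$seed, "train")),
    config$train))

  say("[evaluate] %d test samples", length(te))
  probs <- predict_prob(fit, x_te)
  report <- evaluate_scores(probs, y_te, threshold = config$eval$threshold,
                            B = config$eval$B,
                            seed = derive_seed(config$seed, "eval"))
  scores <- tibble::tibble(patient_id = names(te), score = probs,
                           label = y_te, model_name = config$model$variant)

  saliency <- NULL
  if ((config$explain$n_examples %||% 0) > 0 &&
      config$model$variant != "fwam_only") {
    say("[explain]")
    k <- min(config$explain$n_examples, length(te))
    saliency <- lapply(seq_len(k), function(i) {
      grad_cam(fit, x_te[[i]], class_index = y_te[i])
    })
  }

  if (!is.null(out_dir)) {
    utils::write.csv(split$assignment,
                     file.path(out_dir, sprintf("split_%s.csv", hash)),
                     row.names = FALSE)
    utils::write.csv(fit$history,
                     file.path(out_dir, sprintf("history_%s.csv", hash)),
                     row.names = FALSE)
    utils::write.csv(scores,
                     file.path(out_dir, sprintf("scores_%s.csv", hash)),
                     row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = hash, seed = config$seed,
           n_train = length(tr), n_val = length(va), n_test = length(te),
           metrics = as.list(stats::setNames(report$estimate, report$metric))),
      file.path(out_dir, sprintf("report_%s.json", hash)),
      auto_unbox = TRUE, digits = NA)
    if (!is.null(saliency)) {
      for (i in seq_along(saliency)) {
        ov <- overlay(saliency[[i]]$maps[[1]], x_te[[i]]$values[, , 1])
        write_overlay_png(ov, file.path(out_dir, sprintf("saliency_%s_%d.png", hash, i)))
      }
    }
  }

  list(cohort = cohort, split = split, stats = stats, fit = fit,
       report = report, scores = scores, saliency = saliency,
       config_hash = hash)
}
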