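# Cohort evaluation: stratified splitting, confusion metrics, rank-based
# ROC/AUC, stratified bootstrap CIs, DeLong tests with Bonferroni correction.
# The invasive class (MIBC, label 1) is the designated positive class; the
# non-invasive class is negative. Per-class recalls are always reported so
# "sensitivity for the non-invasive class" is directly readable.

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Stratified cohort split
#'
#' Seeded assignment of ids to training/validation/testing, stratified by
#' class so per-split class fractions stay within one sample of the cohort
#' fraction. Explicit `counts` (summing to the cohort size) override the
#' ratio.
#'
#' @param ids Character or integer sample ids.
#' @param labels Binary labels aligned with `ids`.
#' @param ratio Target proportions (train, val, test); default 6:1:3.
#' @param counts Optional explicit integer counts (train, val, test).
#' @param seed Integer seed.
#' @return A `cohort_split`: list with `train_ids`, `val_ids`, `test_ids`
#'   and an `assignment` tibble.
#' @export
split_cohort <- function(ids, labels, ratio = c(6, 1, 3) / 10,
                         counts = NULL, seed = 1L) {
  n <- length(ids)
  assert_that(length(labels) == n && n > 0, "ids and labels must match")
  if (!is.null(counts)) {
    assert_that(length(counts) == 3 && sum(counts) == n,
                "counts must have 3 entries summing to the cohort size")
    target <- counts
  } else {
    ratio <- ratio / sum(ratio)
    target <- floor(n * ratio)
    rem <- n - sum(target)
    if (rem > 0) {
      o <- order(n * ratio - target, decreasing = TRUE)
      target[o[seq_len(rem)]] <- target[o[seq_len(rem)]] + 1
    }
  }
  split_lab <- rep(NA_character_, n)
  with_seed(seed, {
    # allocate per class with largest-remainder apportionment against the
    # running split totals, then assign shuffled members
    remaining <- target
    classes <- sort(unique(labels), decreasing = TRUE)
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      members <- which(labels == cl)
      members <- members[sample(length(members))]
      if (ci == length(classes)) {
        alloc <- remaining
      } else {
        frac <- length(members) * target / n
        alloc <- floor(frac)
        rem <- length(members) - sum(alloc)
        if (rem > 0) {
          o <- order(frac - alloc, decreasing = TRUE)
          alloc[o[seq_len(rem)]] <- alloc[o[seq_len(rem)]] + 1
        }
        alloc <- pmin(alloc, remaining)
        # any shortfall from the cap goes to the roomiest split
        short <- length(members) - sum(alloc)
        while (short > 0) {
          j <- which.max(remaining - alloc)
          alloc[j] <- alloc[j] + 1
          short <- short - 1
        }
      }
      pos <- c(0, cumsum(alloc))
      for (s in 1:3) {
        if (alloc[s] > 0) {
          split_lab[members[(pos[s] + 1):pos[s + 1]]] <-
            c("train", "val", "test")[s]
        }
      }
      remaining <- remaining - alloc
    }
  })
  assignment <- tibble::tibble(id = ids, label = labels, split = split_lab)
  structure(list(
    train_ids = ids[split_lab == "train"],
    val_ids = ids[split_lab == "val"],
    test_ids = ids[split_lab == "test"],
    assignment = assignment
  ), class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("cohort_split: train %d / val %d / test %d\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids)))
  invisible(x)
}

#' Confusion metrics at a threshold
#'
#' Sensitivity `TP/(TP+FN)` for the designated positive class (invasive by
#' default), specificity, accuracy, and both per-class recalls.
#'
#' @param scores Predicted scores or probabilities.
#' @param labels Binary labels (1 = positive class).
#' @param threshold Decision threshold (default 0.5).
#' @return One-row tibble.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  assert_that(length(scores) == length(labels), "length mismatch")
  assert_that(length(unique(labels)) == 2,
              "both classes must be present; metrics undefined otherwise")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  tibble::tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(labels),
    recall_positive = tp / (tp + fn),
    recall_negative = tn / (tn + fp),
    n_pos = tp + fn, n_neg = tn + fp,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Rank-based ROC curve and AUC
#'
#' AUC via the Mann-Whitney statistic with tie correction (ties count one
#' half); the ROC curve enumerates every distinct score threshold.
#'
#' @param scores Predicted scores.
#' @param labels Binary labels (1 = positive).
#' @return A `roc_result`: list with `auc` and a `curve` tibble (threshold,
#'   fpr, tpr).
#' @export
roc_auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  assert_that(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / n0, 0)
  structure(list(auc = auc,
                 curve = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d curve points)\n",
              x$auc, nrow(x$curve)))
  invisible(x)
}

# Trapezoidal area under the enumerated ROC curve (cross-check path).
roc_trapezoid <- function(roc) {
  cv <- roc$curve
  # ties in scores need the trapezoid (not step) rule, which rank AUC matches
  sum(diff(cv$fpr) * (utils::head(cv$tpr, -1) + utils::tail(cv$tpr, -1)) / 2)
}

#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Stratified bootstrap percentile confidence interval
#'
#' Resamples within each class (so both classes are always present), applies
#' `metric` and returns the percentile interval. Degenerate resamples (metric
#' returns `NA`) are skipped and counted.
#'
#' @param scores,labels As in [roc_auc()].
#' @param metric Function `(scores, labels) -> scalar`, or one of `"auc"`,
#'   `"sensitivity"`, `"specificity"`, `"accuracy"`.
#' @param B Bootstrap replicates (>= 100).
#' @param conf Confidence level.
#' @param seed Integer seed.
#' @return List with `low`, `high`, `point`, `n_skipped`.
#' @export
bootstrap_ci <- function(scores, labels, metric = "auc", B = 2000,
                         conf = 0.95, seed = 1L) {
  assert_that(B >= 100, "B must be at least 100")
  f <- if (is.function(metric)) {
    metric
  } else {
    switch(metric,
      auc = function(s, l) roc_auc(s, l)$auc,
      sensitivity = function(s, l) confusion_metrics(s, l)$sensitivity,
      specificity = function(s, l) confusion_metrics(s, l)$specificity,
      accuracy = function(s, l) confusion_metrics(s, l)$accuracy,
      rlang::abort("unknown metric"))
  }
  i1 <- which(labels == 1); i0 <- which(labels == 0)
  point <- f(scores, labels)
  vals <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- c(sample(i1, length(i1), replace = TRUE),
               sample(i0, length(i0), replace = TRUE))
      tryCatch(f(scores[idx], labels[idx]), error = function(e) NA_real_)
    }, numeric(1))
  })
  ok <- vals[is.finite(vals)]
  alpha <- (1 - conf) / 2
  qs <- quantile(ok, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(low = qs[1], high = qs[2], point = point,
       n_skipped = sum(!is.finite(vals)))
}

# Mid-rank placement components of the DeLong construction.
delong_components <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  v10 <- vapply(x, function(xi) (sum(y < xi) + 0.5 * sum(y == xi)) / n, 0)
  v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m, 0)
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' DeLong test for two correlated AUCs
#'
#' Nonparametric comparison of paired ROC curves via the asymptotic
#' covariance of the Mann-Whitney AUC estimators; two-sided p-value with
#' Bonferroni adjustment `p_adj = min(1, m_comparisons * p)`.
#'
#' @param scores_a,scores_b Paired scores for the same samples.
#' @param labels Binary labels (1 = positive).
#' @param m_comparisons Number of comparisons in the Bonferroni family.
#' @return One-row tibble: auc_a, auc_b, z, p_raw, p_adjusted, m_comparisons.
#' @export
delong_test <- function(scores_a, scores_b, labels, m_comparisons = 1) {
  assert_that(length(scores_a) == length(scores_b) &&
                length(scores_a) == length(labels),
              "scores must be paired on identical samples")
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- ca$m; n <- ca$n
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (var_diff <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (ca$auc - cb$auc) / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  tibble::tibble(auc_a = ca$auc, auc_b = cb$auc, z = z, p_raw = p,
                 p_adjusted = min(1, m_comparisons * p),
                 m_comparisons = as.integer(m_comparisons))
}

#' Cohort summary table
#'
#' Counts and percentages (rounded half-up to one decimal) per class, within
#' optional strata.
#'
#' @param labels Factor-like group labels.
#' @param strata Optional stratifying variable.
#' @return Tibble with group, (stratum,) count, percent.
#' @export
cohort_summary <- function(labels, strata = NULL) {
  assert_that(length(labels) > 0, "empty cohort")
  if (is.null(strata)) {
    tb <- table(factor(labels))
    tibble::tibble(group = names(tb),
                   count = as.integer(tb),
                   percent = round_half_up(100 * as.integer(tb) / length(labels), 1))
  } else {
    df <- tibble::tibble(group = labels, stratum = strata)
    dplyr::ungroup(dplyr::mutate(
      dplyr::summarise(dplyr::group_by(df, .data$stratum, .data$group),
                       count = dplyr::n(), .groups = "drop_last"),
      percent = round_half_up(100 * .data$count / sum(.data$count), 1)))
  }
}

#' Full evaluation report for one model's scores
#'
#' Confusion metrics at the threshold, rank-based AUC, and stratified
#' bootstrap confidence intervals for each metric.
#'
#' @param scores,labels As in [roc_auc()].
#' @param threshold Decision threshold.
#' @param B Bootstrap replicates.
#' @param seed Integer seed.
#' @return An `eval_report` tibble: one row per metric with point estimate
#'   and CI bounds.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5, B = 2000,
                            seed = 1L) {
  cm <- confusion_metrics(scores, labels, threshold)
  auc <- roc_auc(scores, labels)$auc
  metrics <- c("sensitivity", "specificity", "accuracy", "auc")
  pts <- c(cm$sensitivity, cm$specificity, cm$accuracy, auc)
  rows <- lapply(seq_along(metrics), function(i) {
    ci <- bootstrap_ci(scores, labels, metrics[i], B = B, seed = derive_seed(seed, metrics[i]))
    tibble::tibble(metric = metrics[i], estimate = pts[i],
                   ci_low = ci$low, ci_high = ci$high)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_pos") <- cm$n_pos
  attr(out, "n_neg") <- cm$n_neg
  class(out) <- c("eval_report", class(out))
  out
}

#' Pairwise DeLong comparison of several models' score sets
#'
#' @param score_table Tibble with columns `patient_id`, `score`, `label`,
#'   `model_name` (paired across models).
#' @param bonferroni_m Comparisons in the Bonferroni family; defaults to the
#'   number of pairs.
#' @return Tibble of pairwise DeLong results.
#' @export
compare_models <- function(score_table, bonferroni_m = NULL) {
  models <- unique(score_table$model_name)
  assert_that(length(models) >= 2, "need at least two models")
  pairs <- utils::combn(models, 2, simplify = FALSE)
  m <- bonferroni_m %||% length(pairs)
  rows <- lapply(pairs, function(pr) {
    a <- score_table[score_table$model_name == pr[1], ]
    b <- score_table[score_table$model_name == pr[2], ]
    b <- b[match(a$patient_id, b$patient_id), ]
    res <- delong_test(a$score, b$score, a$label, m_comparisons = m)
    dplyr::mutate(res, model_a = pr[1], model_b = pr[2], .before = 1)
  })
  dplyr::bind_rows(rows)
}
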