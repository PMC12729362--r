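# Evaluation statistics: splitting, confusion metrics, ROC/AUC, bootstrap,
# DeLong, cohort summaries.

test_that("explicit counts reproduce the published cohort sizes", {
  set.seed(1)
  labels <- c(rep(1, 48), rep(0, 136))
  ids <- sprintf("P%03d", seq_along(labels))
  sp <- split_cohort(ids, labels, counts = c(115, 20, 49), seed = 4)
  expect_length(sp$train_ids, 115)
  expect_length(sp$val_ids, 20)
  expect_length(sp$test_ids, 49)
  expect_identical(sort(c(sp$train_ids, sp$val_ids, sp$test_ids)), sort(ids))

  sp2 <- split_cohort(ids, labels, counts = c(115, 20, 49), seed = 4)
  expect_identical(sp$assignment, sp2$assignment)
  expect_error(split_cohort(ids, labels, counts = c(200, 20, 49)), "summing")
})

test_that("stratification keeps per-split class fractions within one sample", {
  labels <- c(rep(1, 48), rep(0, 136))
  ids <- seq_along(labels)
  for (seed in 1:5) {
    sp <- split_cohort(ids, labels, counts = c(115, 20, 49), seed = seed)
    df <- sp$assignment
    for (s in c("train", "val", "test")) {
      sub <- df[df$split == s, ]
      expected <- nrow(sub) * 48 / 184
      expect_lte(abs(sum(sub$label) - expected), 1)
    }
  }
})

test_that("confusion metrics match hand arithmetic", {
  # TP = 9, FN = 1, TN = 7, FP = 3
  labels <- c(rep(1, 10), rep(0, 10))
  scores <- c(rep(0.9, 9), 0.1, rep(0.2, 7), rep(0.8, 3))
  cm <- confusion_metrics(scores, labels)
  expect_equal(cm$sensitivity, 0.9)
  expect_equal(cm$specificity, 0.7)
  expect_equal(cm$accuracy, 0.8)
  expect_equal(cm$recall_negative, 0.7)
  # accuracy identity
  expect_equal(cm$accuracy,
               (cm$sensitivity * cm$n_pos + cm$specificity * cm$n_neg) /
                 (cm$n_pos + cm$n_neg))
  # perfect scores
  cmp <- confusion_metrics(labels, labels)
  expect_equal(c(cmp$sensitivity, cmp$specificity, cmp$accuracy), c(1, 1, 1))
  expect_error(confusion_metrics(scores, rep(1, 20)), "both classes")
})

test_that("rank-based AUC handles separation, ties, and random scores", {
  labels <- c(rep(0, 5), rep(1, 5))
  expect_equal(roc_auc(c(1:5, 6:10), labels)$auc, 1)
  expect_equal(roc_auc(rep(1, 10), labels)$auc, 0.5)
  set.seed(6)
  big <- roc_auc(rnorm(1e4), rbinom(1e4, 1, 0.3))
  expect_equal(big$auc, 0.5, tolerance = 0.02)
})

test_that("rank AUC equals trapezoidal ROC integration and pROC", {
  set.seed(7)
  for (i in 1:5) {
    n <- 60
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n) + labels  # informative scores, with a tied variant
    if (i == 3) scores <- round(scores)  # force ties
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, windmri:::roc_trapezoid(r), tolerance = 1e-10)
    expect_equal(r$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
                 tolerance = 1e-10)
  }
  expect_s3_class(autoplot(roc_auc(rnorm(20), rep(c(0, 1), 10))), "ggplot")
})

test_that("stratified bootstrap intervals cover the point estimate and shrink with n", {
  set.seed(8)
  make <- function(n) {
    labels <- rep(c(0, 1), length.out = n)
    list(s = rnorm(n) + 0.8 * labels, l = labels)
  }
  d50 <- make(50); d500 <- make(500)
  ci50 <- bootstrap_ci(d50$s, d50$l, "auc", B = 400, seed = 1)
  ci500 <- bootstrap_ci(d500$s, d500$l, "auc", B = 400, seed = 1)
  expect_lte(ci50$low, ci50$point)
  expect_gte(ci50$high, ci50$point)
  expect_lt(ci500$high - ci500$low, ci50$high - ci50$low)
  ci_b <- bootstrap_ci(d50$s, d50$l, "auc", B = 400, seed = 1)
  expect_identical(c(ci50$low, ci50$high), c(ci_b$low, ci_b$high))
  expect_error(bootstrap_ci(d50$s, d50$l, "auc", B = 50), "at least 100")
})

test_that("DeLong agrees with pROC and degenerates correctly", {
  set.seed(9)
  labels <- rbinom(80, 1, 0.4)
  base <- rnorm(80) + labels
  a <- base + rnorm(80, sd = 0.5)
  b <- base + rnorm(80, sd = 0.5)
  res <- delong_test(a, b, labels)
  pr <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE),
                       pROC::roc(labels, b, quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(res$p_raw, pr$p.value, tolerance = 1e-9)
  expect_equal(abs(res$z), abs(as.numeric(pr$statistic)), tolerance = 1e-9)

  same <- delong_test(a, a, labels)
  expect_equal(same$z, 0)
  expect_equal(same$p_raw, 1)

  capped <- delong_test(a, b, labels, m_comparisons = 4)
  expect_equal(capped$p_adjusted, min(1, 4 * capped$p_raw))
  expect_equal(delong_test(a, b, labels, m_comparisons = 1000)$p_adjusted, 1)
  expect_error(delong_test(a[1:10], b, labels), "paired")
})

test_that("DeLong p-values match a paired permutation oracle", {
  # permutation oracle: swap the two models' scores per sample at random
  perm_p <- function(a, b, labels, n_perm = 2000, seed = 1) {
    windmri:::with_seed(seed, {
      d_obs <- abs(roc_auc(a, labels)$auc - roc_auc(b, labels)$auc)
      n <- length(a)
      hits <- 0
      for (i in seq_len(n_perm)) {
        swap <- runif(n) < 0.5
        ap <- ifelse(swap, b, a)
        bp <- ifelse(swap, a, b)
        d <- abs(roc_auc(ap, labels)$auc - roc_auc(bp, labels)$auc)
        if (d >= d_obs - 1e-12) hits <- hits + 1
      }
      hits / n_perm
    })
  }
  set.seed(10)
  for (i in 1:3) {
    labels <- rep(c(0, 1), each = 25)
    base <- rnorm(50) + 0.8 * labels
    a <- base + rnorm(50, sd = 0.6)
    b <- base + rnorm(50, sd = 0.6)
    p_dl <- delong_test(a, b, labels)$p_raw
    p_pm <- perm_p(a, b, labels, n_perm = 2000, seed = i)
    # agreement within Monte-Carlo error of the permutation estimate
    se <- sqrt(p_pm * (1 - p_pm) / 2000)
    expect_lt(abs(p_dl - p_pm), 4 * se + 0.05)
  }
})

test_that("cohort summary reproduces printed percentages", {
  labels <- c(rep("NMIBC", 136), rep("MIBC", 48))
  sm <- cohort_summary(labels)
  expect_equal(sm$percent[sm$group == "NMIBC"], 73.9)
  expect_equal(sm$percent[sm$group == "MIBC"], 26.1)
  sm0 <- cohort_summary(factor(rep("a", 10), levels = c("a", "b")))
  expect_false("b" %in% sm0$group)
  # zero-count via explicit table path
  expect_equal(windmri:::round_half_up(0 / 10 * 100, 1), 0)
  expect_equal(windmri:::round_half_up(73.85, 1), 73.9)  # half-up, not banker's
})

test_that("evaluate_scores and compare_models assemble tidy reports", {
  set.seed(11)
  labels <- rep(c(0, 1), each = 20)
  s1 <- rnorm(40) + labels
  s2 <- rnorm(40) + 0.5 * labels
  rep1 <- evaluate_scores(s1, labels, B = 200, seed = 1)
  expect_s3_class(rep1, "eval_report")
  expect_identical(rep1$metric, c("sensitivity", "specificity", "accuracy", "auc"))
  expect_true(all(rep1$ci_low <= rep1$estimate + 1e-12))
  expect_true(all(rep1$ci_high >= rep1$estimate - 1e-12))

  tb <- tibble::tibble(
    patient_id = rep(sprintf("P%02d", 1:40), 2),
    score = c(s1, s2),
    label = rep(labels, 2),
    model_name = rep(c("m1", "m2"), each = 40))
  cmp <- compare_models(tb)
  expect_identical(nrow(cmp), 1L)
  expect_identical(cmp$m_comparisons, 1L)
})
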