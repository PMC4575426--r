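test_that("confusion metrics match the defining formulas", {
  perfect <- confusion_metrics(c(rep("interacting", 5), rep("non-interacting", 5)),
                               c(rep(0.9, 5), rep(0.1, 5)))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)

  chance <- confusion_from_counts(1, 1, 1, 1)
  expect_equal(chance$sensitivity, 0.5)
  expect_equal(chance$specificity, 0.5)
  expect_equal(chance$accuracy, 0.5)
  expect_equal(chance$mcc, 0)

  got <- confusion_from_counts(18, 19, 300, 4)
  want <- metrics_formula_oracle(tp = 18, fp = 19, tn = 300, fn = 4)
  expect_equal(got$sensitivity, want$sensitivity)
  expect_equal(got$specificity, want$specificity)
  expect_equal(got$accuracy, want$accuracy)
  expect_equal(got$mcc, want$mcc)

  set.seed(2)
  for (i in 1:20) {
    cnt <- sample(1:50, 4)
    got <- confusion_from_counts(cnt[1], cnt[2], cnt[3], cnt[4])
    want <- metrics_formula_oracle(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(got$mcc, want$mcc)
    expect_equal(got$accuracy, want$accuracy)
  }

  degenerate <- confusion_from_counts(0, 3, 5, 0)
  expect_equal(degenerate$sensitivity, 0)
  expect_true(degenerate$degenerate)
  expect_error(confusion_metrics(character(0), numeric(0)),
               class = "tcsmeta_data_error")
})

test_that("MCC is invariant under a simultaneous class and prediction swap", {
  set.seed(8)
  for (i in 1:10) {
    cnt <- sample(1:40, 4)
    direct <- confusion_from_counts(cnt[1], cnt[2], cnt[3], cnt[4])$mcc
    swapped <- confusion_from_counts(cnt[3], cnt[4], cnt[1], cnt[2])$mcc
    expect_equal(direct, swapped)
  }
})

test_that("AUC equals the pairwise-comparison oracle and handles ties", {
  labels <- c(rep("interacting", 4), rep("non-interacting", 6))
  sep <- roc_auc(labels, c(0.9, 0.8, 0.85, 0.95, 0.1, 0.2, 0.3, 0.15, 0.05, 0.25))
  expect_equal(sep$auc, 1.0)

  expect_equal(roc_auc(labels, rep(0.5, 10))$auc, 0.5)

  set.seed(3)
  for (i in 1:15) {
    n_pos <- sample(3:10, 1)
    n_neg <- sample(3:10, 1)
    scores <- round(runif(n_pos + n_neg), 1)  # rounding forces ties
    lab <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
    expect_equal(roc_auc(lab, scores)$auc,
                 auc_pairwise_oracle(scores[lab], scores[!lab]))
  }

  expect_error(roc_auc(rep("interacting", 4), runif(4)),
               class = "tcsmeta_data_error")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  lab <- c(rep(1, 20), rep(0, 30))
  scores <- rnorm(50, mean = lab)
  expect_equal(roc_auc(lab, scores)$auc,
               as.numeric(pROC::auc(pROC::roc(lab, scores, quiet = TRUE,
                                              direction = "<"))))
})

test_that("score negation mirrors the AUC on tie-free data", {
  set.seed(6)
  lab <- c(rep(TRUE, 10), rep(FALSE, 10))
  scores <- sample(seq(0.01, 0.99, length.out = 20))
  expect_equal(roc_auc(lab, scores)$auc + roc_auc(lab, -scores)$auc, 1)
})

test_that("ROC curves are monotone staircases from sorted thresholds", {
  set.seed(15)
  lab <- rbinom(40, 1, 0.4)
  lab[1:2] <- c(0, 1)
  scores <- round(runif(40), 2)
  curve <- tidy(roc_auc(lab, scores))
  expect_true(all(diff(curve$tpr) >= 0))
  expect_true(all(diff(curve$fpr) >= 0))
  expect_equal(curve$tpr[1], 0)
  expect_equal(curve$tpr[nrow(curve)], 1)
})

test_that("stratified folds are balanced, disjoint, covering and reproducible", {
  data <- tibble::tibble(label = c(rep("interacting", 10), rep("non-interacting", 90)))
  folds <- kfold_split(data, k = 10, seed = 4)
  pos_per_fold <- vapply(folds, function(idx) sum(idx <= 10), integer(1))
  expect_true(all(pos_per_fold == 1))
  expect_equal(sort(unlist(folds)), 1:100)
  expect_equal(anyDuplicated(unlist(folds)), 0)

  expect_identical(folds, kfold_split(data, k = 10, seed = 4))
  expect_false(identical(folds, kfold_split(data, k = 10, seed = 5)))

  tiny <- tibble::tibble(label = c(rep("interacting", 3), rep("non-interacting", 20)))
  expect_warning(kfold_split(tiny, k = 5, seed = 1), "fewer than k")
  expect_error(kfold_split(tiny, k = 30, seed = 1), class = "tcsmeta_data_error")
})

test_that("cross-validation separates separable data and finishes leave-one-out", {
  ft <- simulate_feature_table(n_positive = 20, n_negative = 80,
                               class_separation = 5, seed = 5)
  cv <- cross_validate(ft, k = 5, seed = 2, c_grid = 2^(0:3), g_grid = 2^(-3:0),
                       inner_k = 3)
  expect_equal(cv$auc_pooled, 1.0)
  expect_equal(nrow(cv$scores), 100)
  expect_equal(nrow(tidy(cv)), 5)
  expect_equal(glance(cv)$k, 5)

  small <- simulate_feature_table(n_positive = 8, n_negative = 12,
                                  class_separation = 5, seed = 7)
  suppressWarnings(
    loo <- cross_validate(small, k = 20, seed = 1, c_grid = 2, g_grid = 0.25,
                          inner_k = 2)
  )
  expect_equal(nrow(loo$scores), 20)
})

test_that("cross-validation stays at chance on signal-free data", {
  aucs <- vapply(1:5, function(s) {
    ft <- simulate_feature_table(n_positive = 15, n_negative = 45,
                                 class_separation = 0, seed = 100 + s)
    cross_validate(ft, k = 5, seed = s, c_grid = 2^(0:2), g_grid = 2^(-2:0),
                   inner_k = 3)$auc_pooled
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("protein-level orthogonalization drops leaking training pairs per fold", {
  ft <- simulate_feature_table(n_positive = 15, n_negative = 45,
                               class_separation = 5, seed = 8)
  ft$hk_id <- paste0("h", rep(1:20, 3))
  ft$rr_id <- paste0("r", seq_len(60))
  cv <- cross_validate(ft, k = 3, seed = 1, c_grid = 2^(0:2), g_grid = 2^(-2:0),
                       inner_k = 3, orthogonalize_proteins = TRUE)
  expect_s3_class(cv, "tcs_cv")
  expect_equal(nrow(cv$scores), 60)
})

test_that("the paired ROC comparison behaves on identical, swapped and separated scores", {
  set.seed(9)
  lab <- c(rep(1, 30), rep(0, 70))
  s <- rnorm(100, mean = lab)
  same <- compare_roc(lab, s, s)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p_value, 1)

  s2 <- rnorm(100, mean = 0.3 * lab)
  ab <- compare_roc(lab, s, s2)
  ba <- compare_roc(lab, s2, s)
  expect_equal(ab$delta_auc, -ba$delta_auc)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("the paired AUC test agrees with an independent DeLong implementation", {
  skip_if_not_installed("pROC")
  set.seed(10)
  lab <- c(rep(1, 25), rep(0, 40))
  sa <- rnorm(65, mean = 1.2 * lab)
  sb <- rnorm(65, mean = 0.4 * lab)
  mine <- compare_roc(lab, sa, sb)
  ref <- pROC::roc.test(pROC::roc(lab, sa, quiet = TRUE, direction = "<"),
                        pROC::roc(lab, sb, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(mine$p_value, as.numeric(ref$p.value), tolerance = 1e-8)
  expect_equal(mine$auc_a - mine$auc_b,
               as.numeric(ref$estimate[1] - ref$estimate[2]), tolerance = 1e-10)
})
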