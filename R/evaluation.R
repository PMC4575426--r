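positive_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels > 0)
  label_factor(labels) == "interacting"
}

#' Confusion-matrix metrics at a score threshold
#'
#' Thresholds the scores (predicted interacting when `score >= threshold`)
#' and reports the four counts together with sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, accuracy `(TP+TN)/(TP+TN+FP+FN)` and the
#' Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. Any metric with
#' a zero denominator is reported as 0 and flagged in the `degenerate`
#' column, keeping result tables numeric.
#'
#' @param labels `"interacting"`/`"non-interacting"` (or logical/0-1).
#' @param scores numeric scores in `[0, 1]`.
#' @param threshold classification threshold on the score (default 0.5).
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`, `mcc`, `threshold`, `degenerate`.
#' @export
confusion_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  if (length(labels) == 0) abort("empty input", class = "tcsmeta_data_error")
  pos <- positive_logical(labels)
  pred <- scores >= threshold
  confusion_from_counts(
    tp = sum(pred & pos), fp = sum(pred & !pos),
    tn = sum(!pred & !pos), fn = sum(!pred & pos),
    threshold = threshold
  )
}

#' Metrics from explicit confusion counts
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @param threshold recorded threshold (informational).
#' @return As [confusion_metrics()].
#' @export
confusion_from_counts <- function(tp, fp, tn, fn, threshold = NA_real_) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  degenerate <- (tp + fn) == 0 || (tn + fp) == 0 || mcc_den == 0
  tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    accuracy = safe_div(tp + tn, tp + tn + fp + fn),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
    threshold = threshold,
    degenerate = degenerate
  )
}

#' ROC curve and AUC
#'
#' The AUC is the probability that a random interacting pair outscores a
#' random non-interacting pair, ties counted half:
#' `AUC = P(s+ > s-) + 0.5 * P(s+ = s-)`, computed exactly via the
#' Mann-Whitney rank form. The curve sweeps the sorted unique scores as
#' thresholds (predict positive at `score >= t`), so tied scores appear as
#' a single diagonal segment and trapezoidal integration of the curve
#' equals the rank-based AUC.
#'
#' @param labels `"interacting"`/`"non-interacting"` (or logical/0-1);
#'   both classes must be present.
#' @param scores numeric scores.
#' @return An object of class `tcs_roc`: list with `points` (tibble of
#'   `threshold`, `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  pos <- positive_logical(labels)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("both classes must be present to build a ROC curve",
          class = "tcsmeta_data_error")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- tibble(
    threshold = c(Inf, thr),
    tpr = c(0, vapply(thr, function(t) sum(pos & scores >= t) / n_pos, numeric(1))),
    fpr = c(0, vapply(thr, function(t) sum(!pos & scores >= t) / n_neg, numeric(1)))
  )
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "tcs_roc")
}

#' @export
print.tcs_roc <- function(x, ...) {
  cat(sprintf("<tcs_roc> AUC = %.4f (%d interacting vs %d non-interacting)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @describeIn roc_auc `tidy()` returns the curve points.
#' @param x a `tcs_roc`.
#' @param ... unused.
#' @export
tidy.tcs_roc <- function(x, ...) x$points

#' @describeIn roc_auc `glance()` returns a one-row summary.
#' @export
glance.tcs_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Stratified k-fold assignment
#'
#' Splits row indices into `k` disjoint folds stratified by `label`: within
#' each class, fold sizes differ by at most one. A class with fewer than
#' `k` members is spread as evenly as possible with a warning. Deterministic
#' given `seed`, and independent of row order up to the per-class shuffle.
#'
#' @param data data frame with a `label` column.
#' @param k number of folds (the benchmark protocol uses 5, 10 and 20).
#' @param seed integer seed.
#' @return List of `k` integer vectors of row indices (some possibly empty
#'   when `k` exceeds a class size).
#' @export
kfold_split <- function(data, k = 10, seed = 1) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  n <- nrow(data)
  if (k > n) abort("k exceeds the number of rows", class = "tcsmeta_data_error")
  lab <- as.character(data$label)
  small <- names(which(table(lab) < k))
  if (length(small) > 0) {
    warn(paste0("class(es) with fewer than k members spread as evenly as possible: ",
                paste(small, collapse = ", ")))
  }
  assignment <- integer(n)
  rng_with_seed(seed, {
    for (cl in sort(unique(lab))) {
      idx <- sample(which(lab == cl))
      assignment[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) which(assignment == f))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
rng_with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' k-fold cross-validation of the meta-classifier
#'
#' For each fold, trains on the remaining folds (optionally after
#' protein-level orthogonalization against the held-out fold) and scores
#' the held-out pairs with training-frozen normalization. Reports per-fold
#' confusion metrics and AUC, the pooled ROC over all held-out scores (the
#' headline number), and the fold-mean AUC alongside it.
#'
#' @param features data frame with the six score columns and a `label`
#'   column (e.g. from [feature_table()] joined with labels, or
#'   [simulate_feature_table()]).
#' @param k number of folds.
#' @param seed integer seed driving fold assignment and inner model
#'   selection.
#' @param c_grid,g_grid grids passed to [grid_search_train()].
#' @param inner_k folds of the inner model-selection CV (default 5 to keep
#'   nested CV affordable).
#' @param threshold classification threshold for the per-fold confusion
#'   metrics.
#' @param orthogonalize_proteins when TRUE and the table carries `hk_id` /
#'   `rr_id` columns, training pairs sharing a protein with the held-out
#'   fold are removed before fitting.
#' @param exclude feature columns to drop before training (ablation runs).
#' @return An object of class `tcs_cv`: list with `fold_metrics` (tibble),
#'   `pooled` (one-row tibble of pooled confusion metrics), `roc` (pooled
#'   `tcs_roc`), `auc_pooled`, `auc_fold_mean`, and `scores` (tibble of
#'   held-out `fold`, `label`, `score`).
#' @export
cross_validate <- function(features, k = 10, seed = 1,
                           c_grid = default_c_grid(), g_grid = default_g_grid(),
                           inner_k = 5, threshold = 0.5,
                           orthogonalize_proteins = FALSE,
                           exclude = character(0)) {
  features <- as_tibble(features)
  stopifnot("label" %in% names(features))
  if (length(exclude) > 0) {
    features <- features[, setdiff(names(features), exclude), drop = FALSE]
  }
  folds <- kfold_split(features, k = k, seed = seed)
  held <- vector("list", k)
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    idx <- folds[[f]]
    if (length(idx) == 0) next
    train <- features[-idx, , drop = FALSE]
    test <- features[idx, , drop = FALSE]
    if (orthogonalize_proteins && all(c("hk_id", "rr_id") %in% names(features))) {
      test_prot <- unique(c(test$hk_id, test$rr_id))
      train <- train %>% filter(!.data$hk_id %in% test_prot, !.data$rr_id %in% test_prot)
    }
    if (length(unique(positive_logical(train$label))) < 2) {
      abort(sprintf("fold %d leaves single-class training data", f),
            class = "tcsmeta_data_error")
    }
    m <- grid_search_train(train, train$label, c_grid = c_grid, g_grid = g_grid,
                           k = inner_k, seed = seed + f)
    sc <- predict_score(m, test)
    held[[f]] <- tibble(fold = f, label = test$label, score = sc)
    cm <- confusion_metrics(test$label, sc, threshold = threshold)
    fold_auc <- if (length(unique(positive_logical(test$label))) == 2) {
      roc_auc(test$label, sc)$auc
    } else NA_real_
    fold_rows[[f]] <- mutate(cm, fold = f, auc = fold_auc, c = m$c, g = m$g)
  }
  scores <- bind_rows(held)
  pooled_roc <- roc_auc(scores$label, scores$score)
  structure(
    list(
      fold_metrics = bind_rows(fold_rows) %>% select("fold", dplyr::everything()),
      pooled = confusion_metrics(scores$label, scores$score, threshold = threshold),
      roc = pooled_roc,
      auc_pooled = pooled_roc$auc,
      auc_fold_mean = mean(bind_rows(fold_rows)$auc, na.rm = TRUE),
      scores = scores, k = k, seed = seed
    ),
    class = "tcs_cv"
  )
}

#' @export
print.tcs_cv <- function(x, ...) {
  cat(sprintf("<tcs_cv> %d-fold: pooled AUC = %.4f (fold mean %.4f), pooled MCC = %.3f\n",
              x$k, x$auc_pooled, x$auc_fold_mean, x$pooled$mcc))
  invisible(x)
}

#' @describeIn cross_validate `tidy()` returns the per-fold metrics.
#' @param x a `tcs_cv`.
#' @param ... unused.
#' @export
tidy.tcs_cv <- function(x, ...) x$fold_metrics

#' @describeIn cross_validate `glance()` returns a one-row summary.
#' @export
glance.tcs_cv <- function(x, ...) {
  tibble(k = x$k, auc_pooled = x$auc_pooled, auc_fold_mean = x$auc_fold_mean,
         mcc = x$pooled$mcc, sensitivity = x$pooled$sensitivity,
         specificity = x$pooled$specificity, accuracy = x$pooled$accuracy)
}

#' Paired comparison of two ROC curves (DeLong test)
#'
#' Compares two classifiers scored on the *same* examples using DeLong's
#' nonparametric test on correlated AUCs: the variance of the AUC
#' difference is estimated from the per-example placement components shared
#' between the two score vectors, and a two-sided normal p-value is
#' reported for `delta_auc = auc_a - auc_b`.
#'
#' @param labels shared labels.
#' @param scores_a,scores_b scores of the two classifiers on the same
#'   examples.
#' @return A one-row tibble: `auc_a`, `auc_b`, `delta_auc`, `se`, `z`,
#'   `p_value`.
#' @export
compare_roc <- function(labels, scores_a, scores_b) {
  pos <- positive_logical(labels)
  stopifnot(length(scores_a) == length(pos), length(scores_b) == length(pos))
  xs <- cbind(scores_a, scores_b)[pos, , drop = FALSE]
  ys <- cbind(scores_a, scores_b)[!pos, , drop = FALSE]
  m <- nrow(xs)
  n <- nrow(ys)
  if (m == 0 || n == 0) abort("both classes required", class = "tcsmeta_data_error")
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  # placement values: V10[i, r] = mean_j psi(X_ir, Y_jr); V01[j, r] likewise
  V10 <- sapply(1:2, function(r) vapply(seq_len(m), function(i) mean(psi(xs[i, r], ys[, r])), numeric(1)))
  V01 <- sapply(1:2, function(r) vapply(seq_len(n), function(j) mean(psi(xs[, r], ys[j, r])), numeric(1)))
  aucs <- colMeans(V10)
  S10 <- stats::cov(V10)
  S01 <- stats::cov(V01)
  var_diff <- (S10[1, 1] + S10[2, 2] - 2 * S10[1, 2]) / m +
    (S01[1, 1] + S01[2, 2] - 2 * S01[1, 2]) / n
  delta <- aucs[1] - aucs[2]
  if (var_diff <= .Machine$double.eps) {
    if (abs(delta) > 1e-12) warn("degenerate variance with nonzero AUC difference; p set to 1")
    return(tibble(auc_a = aucs[1], auc_b = aucs[2], delta_auc = delta,
                  se = 0, z = 0, p_value = 1))
  }
  z <- delta / sqrt(var_diff)
  tibble(auc_a = aucs[1], auc_b = aucs[2], delta_auc = delta,
         se = sqrt(var_diff), z = z, p_value = 2 * pnorm(-abs(z)))
}
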