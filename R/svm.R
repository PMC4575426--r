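default_c_grid <- function() 2^seq(-5, 15, by = 2)
default_g_grid <- function() 2^seq(-15, 3, by = 2)

label_factor <- function(labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "interacting", "non-interacting")
  if (is.numeric(labels)) labels <- ifelse(labels > 0, "interacting", "non-interacting")
  bad <- setdiff(unique(labels), c("interacting", "non-interacting"))
  if (length(bad) > 0) {
    abort(paste0("labels must be interacting/non-interacting; got ", bad[1]),
          class = "tcsmeta_data_error")
  }
  factor(labels, levels = c("interacting", "non-interacting"))
}

#' Min-max normalize decision values to [0, 1]
#'
#' `(v - min) / (max - min)`; a constant vector maps to 0.5 everywhere.
#' Rank order is preserved, so thresholding the normalized values is
#' equivalent to thresholding the raw ones.
#'
#' @param v numeric vector of raw decision values.
#' @return Values in `[0, 1]`.
#' @export
normalize_decision_values <- function(v) {
  stopifnot(length(v) >= 1)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(0.5, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

# Raw LIBSVM decision values oriented so that larger = more likely
# interacting, regardless of which class LIBSVM happened to take as its
# reference during training.
decision_values <- function(model, X) {
  pr <- predict(model, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  sgn <- if (startsWith(colnames(dv)[1], "interacting")) 1 else -1
  sgn * as.numeric(dv[, 1])
}

#' Train the class-weighted RBF meta-classifier with a grid search
#'
#' Selects the error cost `c` and RBF width `g` maximizing the mean k-fold
#' cross-validated AUC on the training data (ties broken toward smaller `c`,
#' then smaller `g`), then refits on all data. Class imbalance is handled by
#' weighting the minority class by `N_majority / N_minority` (LIBSVM's
#' per-class `-w` weighting). Decision-value normalization bounds are frozen
#' from the training decision values, so downstream scores are comparable
#' across prediction batches. Deterministic given `seed` (which drives only
#' the fold assignment).
#'
#' @param features data frame with the six score columns (extra columns
#'   ignored), or a numeric matrix.
#' @param labels vector of `"interacting"` / `"non-interacting"` (or
#'   logical/0-1) labels, one per row.
#' @param c_grid,g_grid cost and gamma grids (defaults: the powers-of-two
#'   lattice `2^-5..2^15` and `2^-15..2^3`).
#' @param k folds for the model-selection CV (default 10).
#' @param seed integer seed for the fold assignment.
#' @return An object of class `tcs_svm`: the fitted LIBSVM model plus
#'   `c`, `g`, `class_weights`, `norm_min`, `norm_max`, `cv` (the grid of
#'   mean CV AUCs), `feature_names`, `seed`, `degenerate`.
#' @export
grid_search_train <- function(features, labels,
                              c_grid = default_c_grid(),
                              g_grid = default_g_grid(),
                              k = 10, seed = 1) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  feature_names <- colnames(X) %||% FEATURE_ORDER[seq_len(ncol(X))]
  y <- label_factor(labels)
  stopifnot(nrow(X) == length(y), length(c_grid) >= 1, length(g_grid) >= 1)
  if (any(table(y) < 2) || nlevels(droplevels(y)) < 2) {
    abort("need at least two examples of each class", class = "tcsmeta_data_error")
  }
  counts <- table(y)
  wts <- c(interacting = 1, `non-interacting` = 1)
  minority <- names(counts)[which.min(counts)]
  wts[minority] <- max(counts) / min(counts)

  # canonicalize row order (label, then feature values) so that fold
  # assignment — and hence the whole fit — does not depend on how the
  # caller happened to order the examples
  ord <- do.call(order, c(list(as.integer(y)),
                          lapply(seq_len(ncol(X)), function(j) X[, j])))
  X <- X[ord, , drop = FALSE]
  y <- y[ord]

  folds <- kfold_split(tibble(label = as.character(y)), k = k, seed = seed)
  grid <- expand.grid(g = g_grid, c = c_grid, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$c, grid$g), ]
  cv_auc <- vapply(seq_len(nrow(grid)), function(i) {
    aucs <- vapply(folds, function(idx) {
      ytr <- y[-idx]
      if (nlevels(droplevels(ytr)) < 2 || nlevels(droplevels(y[idx])) < 2) return(NA_real_)
      m <- e1071::svm(X[-idx, , drop = FALSE], ytr, kernel = "radial",
                      cost = grid$c[i], gamma = grid$g[i],
                      class.weights = wts, scale = FALSE)
      dv <- decision_values(m, X[idx, , drop = FALSE])
      roc_auc(y[idx] == "interacting", dv)$auc
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- which(cv_auc >= max(cv_auc) - 1e-12)[1]

  model <- e1071::svm(X, y, kernel = "radial", cost = grid$c[best],
                      gamma = grid$g[best], class.weights = wts, scale = FALSE)
  dv <- decision_values(model, X)
  degenerate <- min(dv) == max(dv)
  if (degenerate) warn("all training decision values equal; normalization is degenerate")
  structure(
    list(model = model, c = grid$c[best], g = grid$g[best],
         class_weights = wts,
         norm_min = min(dv), norm_max = max(dv), degenerate = degenerate,
         cv = as_tibble(grid) %>% mutate(cv_auc = cv_auc) %>% select("c", "g", "cv_auc"),
         cv_auc = cv_auc[best],
         feature_names = feature_names,
         n_train = nrow(X), seed = seed),
    class = "tcs_svm"
  )
}

#' @export
print.tcs_svm <- function(x, ...) {
  cat(sprintf(
    "<tcs_svm> RBF meta-classifier: c = %g, g = %g (CV AUC %.3f), %d training pairs\n",
    x$c, x$g, x$cv_auc, x$n_train))
  cat(sprintf("  class weights: interacting %.2f, non-interacting %.2f\n",
              x$class_weights[["interacting"]], x$class_weights[["non-interacting"]]))
  invisible(x)
}

#' Score pairs with a trained meta-classifier
#'
#' Raw decision values are min-max scaled with the bounds frozen at training
#' time and clamped to `[0, 1]`; a monotone transform of the margin, so
#' ranking pairs by score equals ranking by decision value.
#'
#' @param m a trained `tcs_svm`.
#' @param features data frame with the six score columns, or numeric matrix.
#' @return Numeric scores in `[0, 1]`, one per row.
#' @export
predict_score <- function(m, features) {
  stopifnot(inherits(m, "tcs_svm"))
  X <- if (is.matrix(features)) features else feature_matrix(features, cols = m$feature_names)
  if (m$degenerate) {
    warn("degenerate normalization bounds; returning 0.5 for every pair")
    return(rep(0.5, nrow(X)))
  }
  dv <- decision_values(m$model, X)
  pmin(pmax((dv - m$norm_min) / (m$norm_max - m$norm_min), 0), 1)
}

#' @describeIn grid_search_train `tidy()` returns the grid-search surface:
#'   one row per `(c, g)` with its mean CV AUC.
#' @param x a `tcs_svm`.
#' @param ... unused.
#' @export
tidy.tcs_svm <- function(x, ...) x$cv

#' @describeIn grid_search_train `glance()` returns a one-row model summary.
#' @export
glance.tcs_svm <- function(x, ...) {
  tibble(c = x$c, g = x$g, cv_auc = x$cv_auc,
         weight_interacting = x$class_weights[["interacting"]],
         weight_non_interacting = x$class_weights[["non-interacting"]],
         n_support = sum(x$model$nSV), n_train = x$n_train,
         norm_min = x$norm_min, norm_max = x$norm_max, seed = x$seed)
}

#' Save / load a trained meta-classifier
#'
#' The model file is accompanied by a JSON sidecar (`<path>.json`) recording
#' the selected `(c, g)`, class weights, normalization bounds, feature order
#' and seed, so a run's provenance is inspectable as plain text.
#'
#' @param m a `tcs_svm`.
#' @param path output path for the model file.
#' @return `path`, invisibly (`save_model`); the restored `tcs_svm`
#'   (`load_model`).
#' @export
save_model <- function(m, path) {
  stopifnot(inherits(m, "tcs_svm"))
  saveRDS(m, path)
  header <- list(c = m$c, g = m$g,
                 class_weights = as.list(m$class_weights),
                 norm_min = m$norm_min, norm_max = m$norm_max,
                 feature_order = m$feature_names, seed = m$seed,
                 cv_auc = m$cv_auc, n_train = m$n_train)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "tcs_svm")) abort("not a tcs_svm model file", class = "tcsmeta_data_error")
  m
}
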