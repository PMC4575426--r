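#' Plot a ROC curve
#'
#' @param object a `tcs_roc` from [roc_auc()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tcs_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot pooled and per-fold ROC curves of a cross-validation
#'
#' @param object a `tcs_cv` from [cross_validate()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tcs_cv <- function(object, ...) {
  per_fold <- object$scores %>%
    group_by(.data$fold) %>%
    dplyr::group_modify(function(d, key) {
      if (length(unique(positive_logical(d$label))) < 2) return(tibble())
      tidy(roc_auc(d$label, d$score))
    }) %>%
    ungroup()
  p <- ggplot2::ggplot()
  if (nrow(per_fold) > 0) {
    p <- p + ggplot2::geom_step(
      data = per_fold,
      ggplot2::aes(x = .data$fpr, y = .data$tpr, group = .data$fold),
      colour = "grey70", linewidth = 0.3
    )
  }
  p +
    ggplot2::geom_step(data = object$roc$points,
                       ggplot2::aes(x = .data$fpr, y = .data$tpr),
                       linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%d-fold CV: pooled AUC = %.3f", object$k, object$auc_pooled),
      subtitle = "Grey: per-fold curves; black: pooled"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the grid-search surface of a trained meta-classifier
#'
#' @param object a `tcs_svm` from [grid_search_train()].
#' @param ... unused.
#' @return A ggplot object (tile map of mean CV AUC over the c/g lattice).
#' @export
autoplot.tcs_svm <- function(object, ...) {
  ggplot2::ggplot(object$cv,
                  ggplot2::aes(x = log2(.data$c), y = log2(.data$g),
                               fill = .data$cv_auc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = tibble(c = object$c, g = object$g, cv_auc = NA),
                        shape = 4, size = 3, colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "mean CV AUC") +
    ggplot2::labs(x = "log2(cost)", y = "log2(gamma)",
                  title = "Grid search (x marks the selected model)") +
    ggplot2::theme_minimal()
}

#' Class-coloured score distribution for a feature table or scored pairs
#'
#' @param data a data frame with a `label` column and one score column.
#' @param score column name to plot (default `"score"`).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(data, score = "score") {
  ggplot2::ggplot(as_tibble(data),
                  ggplot2::aes(x = .data[[score]], fill = .data$label)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 30) +
    ggplot2::labs(x = score, y = "pairs") +
    ggplot2::theme_minimal()
}
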