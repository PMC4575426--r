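#' Published per-pair scores on the Caulobacter T benchmark
#'
#' The 21-pair Caulobacter crescentus benchmark (16 interacting, 5
#' non-interacting) with the published per-pair scores of a Bayesian TCS
#' pairing predictor and the SVM meta-predictor, as printed; usable for
#' paired ROC comparison without recomputing either method.
#'
#' @return A tibble with columns `hk_id`, `rr_id`, `label`, `bayesian`,
#'   `meta`.
#' @export
t_set_scores <- function() {
  path <- system.file("extdata", "t_set_scores.csv", package = "tcsmeta",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Per-pair prediction wins on the T benchmark
#'
#' For interacting pairs the higher score wins; for non-interacting pairs
#' the lower score wins; equal scores tie.
#'
#' @param scores table from [t_set_scores()] (or same shape).
#' @return A tibble counting `meta`, `bayesian` and `tie` outcomes.
#' @export
t_set_wins <- function(scores = t_set_scores()) {
  better <- ifelse(scores$label == "interacting",
                   sign(scores$meta - scores$bayesian),
                   sign(scores$bayesian - scores$meta))
  tibble(
    winner = c("meta", "bayesian", "tie"),
    n = c(sum(better > 0), sum(better < 0), sum(better == 0))
  )
}
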