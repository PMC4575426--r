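#' Single-feature ablation sweep
#'
#' Quantifies each method's contribution to the meta-classifier by re-running
#' the k-fold cross-validation with one feature excluded at a time (and,
#' optionally, extra named subsets such as dropping both chromosomal-context
#' features together) and comparing pooled AUC/MCC against the full
#' six-feature model. A large drop on exclusion marks an indispensable
#' feature.
#'
#' @param features labelled feature table (as for [cross_validate()]).
#' @param k,seed,c_grid,g_grid,inner_k passed to [cross_validate()].
#' @param extra_subsets named list of character vectors of features to
#'   exclude jointly, e.g. `list("gn+go" = c("gn", "go"))`.
#' @return A tibble with one row per run: `excluded`, `auc_pooled`, `mcc`,
#'   and `delta_auc` relative to the all-features run (first row).
#' @export
ablation_study <- function(features, k = 10, seed = 1,
                           c_grid = default_c_grid(), g_grid = default_g_grid(),
                           inner_k = 5, extra_subsets = list()) {
  present <- intersect(FEATURE_ORDER, names(features))
  runs <- c(list(none = character(0)),
            setNames(as.list(present), present),
            extra_subsets)
  rows <- lapply(names(runs), function(nm) {
    cv <- cross_validate(features, k = k, seed = seed, c_grid = c_grid,
                         g_grid = g_grid, inner_k = inner_k,
                         exclude = runs[[nm]])
    tibble(excluded = nm, auc_pooled = cv$auc_pooled, mcc = cv$pooled$mcc)
  })
  out <- bind_rows(rows)
  out$delta_auc <- out$auc_pooled - out$auc_pooled[1]
  out
}
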