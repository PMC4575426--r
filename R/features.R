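#' Assemble the six-feature vector for one candidate pair
#'
#' Calls the six per-method scorers in the fixed order i2h, MT, GF, PP, GN,
#' GO and assembles their results into one row of the meta-predictor's
#' input table. A scorer returning `NA`, returning a value flagged
#' `missing_evidence`, or throwing, yields a 0 entry with the corresponding
#' mask bit set — the evidence is absent, not negative. The mask itself is
#' not part of the six-dimensional vector fed to the classifier.
#'
#' @param pair a one-row data frame identifying the pair (columns `hk_id`,
#'   `rr_id` at minimum); carried through to the output.
#' @param scorers named list of six zero-argument functions (names `i2h`,
#'   `mt`, `gf`, `pp`, `gn`, `go`), each returning a numeric score or `NA`.
#' @return A one-row tibble: the pair columns, six numeric score columns,
#'   and six logical `missing_*` columns.
#' @export
assemble_features <- function(pair, scorers) {
  if (!all(FEATURE_ORDER %in% names(scorers))) {
    abort(paste0("scorers must be named ", paste(FEATURE_ORDER, collapse = ", ")),
          class = "tcsmeta_data_error")
  }
  vals <- lapply(FEATURE_ORDER, function(f) {
    out <- tryCatch(scorers[[f]](), error = function(e) NA_real_)
    if (isTRUE(attr(out, "missing_evidence"))) out <- NA_real_
    as.numeric(out)[1]
  })
  vals <- setNames(unlist(vals), FEATURE_ORDER)
  miss <- is.na(vals) | !is.finite(vals)
  if (all(miss)) {
    abort(sprintf("pair (%s, %s): all six features missing; pair is unpredictable",
                  pair$hk_id[1], pair$rr_id[1]),
          class = "tcsmeta_unpredictable_pair")
  }
  vals[miss] <- 0
  out <- as_tibble(pair[1, , drop = FALSE])
  for (f in FEATURE_ORDER) out[[f]] <- unname(vals[[f]])
  for (f in FEATURE_ORDER) out[[paste0("missing_", f)]] <- unname(miss[[f]])
  out
}

#' Compute the feature table for a pair dataset
#'
#' Maps [assemble_features()] over a pair dataset, given a factory that
#' builds the six scorers for one pair (closing over MSAs, the reference
#' genome set, configuration, ...). Pairs for which every feature is
#' missing are dropped with a warning and counted in the `n_unpredictable`
#' attribute.
#'
#' @param pairs a pair dataset ([tcs_pairs()]).
#' @param scorer_factory function taking one pair row (a one-row tibble)
#'   and returning the named scorer list for [assemble_features()].
#' @return A tibble with one row per predictable pair.
#' @export
feature_table <- function(pairs, scorer_factory) {
  pairs <- tcs_pairs(pairs)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    row <- as_tibble(pairs)[i, , drop = FALSE]
    tryCatch(assemble_features(row, scorer_factory(row)),
             tcsmeta_unpredictable_pair = function(e) NULL)
  })
  n_bad <- sum(vapply(rows, is.null, logical(1)))
  if (n_bad > 0) warn(sprintf("%d unpredictable pair(s) dropped (all features missing)", n_bad))
  out <- bind_rows(rows)
  attr(out, "n_unpredictable") <- n_bad
  out
}

#' Extract the feature matrix from a feature table
#'
#' @param features a data frame containing score columns named after the
#'   methods (any subset of i2h, mt, gf, pp, gn, go, in that order).
#' @param cols the feature columns to extract; defaults to every method
#'   column present, in the fixed feature order. Supplying fewer than six
#'   supports ablation runs.
#' @return Numeric matrix with the requested columns.
#' @export
feature_matrix <- function(features, cols = NULL) {
  cols <- cols %||% intersect(FEATURE_ORDER, names(features))
  miss <- setdiff(cols, names(features))
  if (length(cols) == 0 || length(miss) > 0) {
    abort(paste0("feature table lacks method column(s): ",
                 paste(if (length(miss)) miss else FEATURE_ORDER, collapse = ", ")),
          class = "tcsmeta_data_error")
  }
  as.matrix(as_tibble(features)[, cols])
}
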