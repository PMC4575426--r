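#' Validate a table of candidate HK-RR pairs
#'
#' A pair dataset is a tibble with one row per candidate histidine
#' kinase / response regulator pairing and columns `hk_id`, `rr_id`,
#' `label` (one of `"interacting"`, `"non-interacting"`, `"unknown"`) and
#' `species`. Labels come from the input only; nothing here infers them.
#'
#' @param pairs a data frame with columns `hk_id`, `rr_id`, `label`,
#'   `species`. An optional logical column `adjacent` is preserved.
#' @param provenance free-text provenance attached as an attribute.
#' @return A validated tibble of class `tcs_pairs`.
#' @export
tcs_pairs <- function(pairs, provenance = NA_character_) {
  stopifnot(is.data.frame(pairs))
  needed <- c("hk_id", "rr_id", "label", "species")
  missing_cols <- setdiff(needed, names(pairs))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "tcsmeta_data_error")
  }
  pairs <- as_tibble(pairs)
  bad <- which(!pairs$label %in% c("interacting", "non-interacting", "unknown"))
  if (length(bad) > 0) {
    abort(sprintf("unknown label %s in row %d", dQuote(pairs$label[bad[1]]), bad[1]),
          class = "tcsmeta_parse_error")
  }
  if (any(pairs$hk_id == pairs$rr_id)) {
    abort("a pair may not have hk_id == rr_id", class = "tcsmeta_data_error")
  }
  dup <- duplicated(pairs[, c("hk_id", "rr_id")])
  if (any(dup)) {
    abort(sprintf("duplicate pair (%s, %s) in row %d",
                  pairs$hk_id[which(dup)[1]], pairs$rr_id[which(dup)[1]], which(dup)[1]),
          class = "tcsmeta_parse_error")
  }
  out <- structure(pairs, class = c("tcs_pairs", class(pairs)))
  attr(out, "provenance") <- provenance
  out
}

#' Read a pair dataset from CSV or TSV
#'
#' Expects columns `hk_id`, `rr_id`, `label`, `species`; extra columns are
#' kept. The delimiter is inferred from the extension (`.tsv` uses tabs).
#'
#' @param path path to the delimited file.
#' @return A `tcs_pairs` tibble; positive/negative counts are queryable with
#'   [pair_counts()].
#' @export
load_pair_dataset <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "tcsmeta_data_error")
  reader <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) readr::read_tsv else readr::read_csv
  raw <- reader(path, show_col_types = FALSE, progress = FALSE)
  tcs_pairs(raw, provenance = path)
}

#' Write a pair dataset as CSV
#'
#' @param pairs a `tcs_pairs` tibble (or any data frame with its columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_dataset <- function(pairs, path) {
  readr::write_csv(as_tibble(pairs), path, progress = FALSE)
  invisible(path)
}

#' Count pairs by label
#'
#' @param pairs a pair dataset.
#' @return A tibble with columns `label` and `n`.
#' @export
pair_counts <- function(pairs) {
  as_tibble(pairs) %>% count(.data$label)
}

#' Split a pair dataset into neighbouring and orphan pairs
#'
#' A pair is *neighbouring* when its two genes are consecutive on the
#' chromosome of the pair's species — no other annotated gene lies between
#' them — and *orphan* otherwise. Pairs whose genes cannot both be located in
#' the supplied annotation go to an `unresolved` bucket with a warning. The
#' three buckets partition the input.
#'
#' Consecutiveness, not a base-pair cutoff, defines the dataset split; the
#' 200-bp intergenic rule belongs to the gene-neighbourhood *feature* (see
#' [neighbourhood_evidence()]), not to dataset construction.
#'
#' @param pairs a pair dataset.
#' @param annotations a named list of [genome_annotation()] objects keyed by
#'   species tag (matching the `species` column).
#' @return A list with `tcs_pairs` elements `neighbouring`, `orphan` and
#'   `unresolved`.
#' @export
split_by_adjacency <- function(pairs, annotations) {
  pairs <- tcs_pairs(pairs)
  bucket <- vapply(seq_len(nrow(pairs)), function(i) {
    ann <- annotations[[pairs$species[i]]]
    if (is.null(ann)) return("unresolved")
    if (genes_consecutive(ann, pairs$hk_id[i], pairs$rr_id[i])) "neighbouring" else {
      if (all(c(pairs$hk_id[i], pairs$rr_id[i]) %in% ann$genes$gene_id)) "orphan" else "unresolved"
    }
  }, character(1))
  if (any(bucket == "unresolved")) {
    warn(sprintf("%d pair(s) with unlocatable genes routed to 'unresolved'",
                 sum(bucket == "unresolved")))
  }
  take <- function(which) {
    sub <- pairs[bucket == which, , drop = FALSE]
    tcs_pairs(as_tibble(sub), provenance = paste0(attr(pairs, "provenance"), " [", which, "]"))
  }
  list(neighbouring = take("neighbouring"), orphan = take("orphan"),
       unresolved = take("unresolved"))
}

# TRUE when both genes exist in the annotation and no other gene starts
# between them along the chromosome (strand-agnostic).
genes_consecutive <- function(ann, id_a, id_b) {
  g <- ann$genes
  ia <- match(id_a, g$gene_id)
  ib <- match(id_b, g$gene_id)
  if (is.na(ia) || is.na(ib)) return(FALSE)
  ord <- order(g$start, g$end)
  abs(match(ia, ord) - match(ib, ord)) == 1L
}

#' Remove training pairs overlapping a test set
#'
#' Prevents information leakage between training and test data. In
#' `mode = "pair"` only exact `(hk_id, rr_id)` matches are dropped; in
#' `mode = "protein"` any training pair sharing *either* protein with any
#' test pair is dropped — the stricter orthogonalization used when a
#' benchmark must not see the test proteins at all.
#'
#' @param train,test pair datasets.
#' @param mode `"pair"` or `"protein"`.
#' @return The retained training rows as a `tcs_pairs` tibble.
#' @export
orthogonalize <- function(train, test, mode = c("pair", "protein")) {
  mode <- match.arg(mode)
  train <- tcs_pairs(train)
  test <- as_tibble(test)
  keep <- if (mode == "pair") {
    !(paste(train$hk_id, train$rr_id, sep = "\r") %in%
        paste(test$hk_id, test$rr_id, sep = "\r"))
  } else {
    test_proteins <- unique(c(test$hk_id, test$rr_id))
    !(train$hk_id %in% test_proteins | train$rr_id %in% test_proteins)
  }
  out <- train[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    abort("orthogonalization removed every training pair", class = "tcsmeta_data_error")
  }
  tcs_pairs(as_tibble(out), provenance = attr(train, "provenance"))
}
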