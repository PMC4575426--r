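AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Amino-acid similarity table for correlated-mutation scoring
#'
#' Returns the symmetric 20x20 similarity table used to turn alignment
#' columns into inter-sequence similarity vectors. The default is BLOSUM62
#' (taken from Biostrings, restricted to the 20 standard residues); any
#' symmetric table can be supplied instead, e.g. via
#' [read_similarity_table()].
#'
#' @param name `"BLOSUM62"`, `"BLOSUM50"` or `"BLOSUM45"`.
#' @return A symmetric numeric matrix with the 20 standard amino acids as
#'   dimnames.
#' @export
similarity_table <- function(name = "BLOSUM62") {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- get(name, envir = env)[AA20, AA20]
  storage.mode(m) <- "double"
  m
}

#' Read a residue similarity table from a labelled TSV
#'
#' The file must be a square matrix with amino-acid single-letter row and
#' column labels; symmetry is checked.
#'
#' @param path path to a TSV with a header row of residue labels and one
#'   labelled row per residue.
#' @return A symmetric numeric matrix.
#' @export
read_similarity_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (!isTRUE(all.equal(m, t(m)))) {
    abort("similarity table must be symmetric", class = "tcsmeta_data_error")
  }
  m
}

# Characters of one alignment side as an n_species x n_columns matrix.
residue_matrix <- function(rows) {
  do.call(rbind, strsplit(unname(rows), ""))
}

#' Inter-sequence similarity vector for one alignment column
#'
#' For a fixed column, emits one entry per unordered pair of sequences
#' `(k, l)` with `k < l`: the similarity-table value for the two residues
#' the sequences carry at that column. Entries where either residue is a gap
#' (or not a standard amino acid) are `NA` (missing). These vectors are the
#' raw material of the correlated-mutation (in-silico two-hybrid) score: two
#' columns co-evolve when their similarity vectors correlate across sequence
#' pairs.
#'
#' @param rows named character vector: one side of a paired alignment.
#' @param column 1-based column index.
#' @param matrix symmetric residue similarity table
#'   (default [similarity_table()]).
#' @return Numeric vector of length `choose(n, 2)` in row-major pair order
#'   ((1,2), (1,3), ..., (n-1,n)).
#' @export
column_similarity_vector <- function(rows, column, matrix = similarity_table()) {
  res <- substr(unname(rows), column, column)
  n <- length(res)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  a <- res[idx[, 1]]
  b <- res[idx[, 2]]
  ok <- a %in% rownames(matrix) & b %in% rownames(matrix)
  out <- rep(NA_real_, nrow(idx))
  out[ok] <- matrix[cbind(a[ok], b[ok])]
  out
}

#' Correlation between two column similarity vectors
#'
#' Pearson correlation over entries present in both vectors. By convention
#' the correlation is 0 — not `NA` — when fewer than `min_overlap` entries
#' are shared or either vector is constant over the shared entries, so that
#' downstream feature vectors stay numeric.
#'
#' @param vec_i,vec_j similarity vectors over the same sequence-pair index.
#' @param min_overlap minimum shared non-missing entries (default 10).
#' @return Correlation in `[-1, 1]`.
#' @export
position_pair_correlation <- function(vec_i, vec_j, min_overlap = 10) {
  stopifnot(length(vec_i) == length(vec_j))
  ok <- !is.na(vec_i) & !is.na(vec_j)
  if (sum(ok) < min_overlap) return(0)
  x <- vec_i[ok]
  y <- vec_j[ok]
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

# Columns informative for covariation: at least two distinct non-gap
# residues and at most max_gap_frac gaps.
variable_columns <- function(res_mat, max_gap_frac = 0.5) {
  vapply(seq_len(ncol(res_mat)), function(j) {
    col <- res_mat[, j]
    non_gap <- col[col %in% AA20]
    length(non_gap) >= (1 - max_gap_frac) * length(col) &&
      length(unique(non_gap)) >= 2
  }, logical(1))
}

#' Correlated-mutation (in-silico two-hybrid) interaction score
#'
#' Scans for compensatory mutations between the two proteins of a paired
#' alignment: for every pair of variable columns (one column from each
#' protein) it computes the Pearson correlation of the two columns'
#' inter-sequence similarity vectors, and returns the fraction of
#' inter-protein column pairs whose correlation reaches `threshold`. A high
#' fraction of strongly correlated column pairs indicates co-evolution and
#' hence a likely physical interaction. The score is symmetric in the two
#' proteins and deterministic.
#'
#' @param pa a [build_paired_alignment()] result.
#' @param threshold correlation cutoff counting a column pair as co-evolving
#'   (default 0.8).
#' @param matrix residue similarity table (default [similarity_table()]).
#' @param min_overlap passed to [position_pair_correlation()].
#' @return Score in `[0, 1]`, or `NA` (missing evidence) when either protein
#'   has no variable columns.
#' @export
i2h_score <- function(pa, threshold = 0.8, matrix = similarity_table(),
                      min_overlap = 10) {
  stopifnot(inherits(pa, "tcs_paired_alignment"))
  va <- column_vectors(pa$rows_a, matrix)
  vb <- column_vectors(pa$rows_b, matrix)
  if (is.null(va) || is.null(vb)) return(NA_real_)
  r <- cross_correlations(va, vb, min_overlap)
  mean(r >= threshold)
}

# All variable-column similarity vectors of one side as a matrix
# (sequence pairs x columns), or NULL when no column is variable.
column_vectors <- function(rows, matrix) {
  rm <- residue_matrix(rows)
  vc <- which(variable_columns(rm))
  if (length(vc) == 0) return(NULL)
  vapply(vc, function(j) column_similarity_vector(rows, j, matrix),
         numeric(choose(length(rows), 2)))
}

# Pearson correlations between every column of A and every column of B
# under the pairwise-missing + zero-variance + short-overlap conventions of
# position_pair_correlation, vectorized.
cross_correlations <- function(A, B, min_overlap = 10) {
  n_shared <- crossprod(!is.na(A), !is.na(B))
  r <- suppressWarnings(cor(A, B, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r[n_shared < min_overlap] <- 0
  r
}

#' Fractional-identity distance matrix across species
#'
#' For every pair of aligned rows, the distance is one minus the fraction of
#' columns with identical residues, counted over columns where neither row
#' has a gap. This cheap, deterministic distance stands in for a
#' phylogenetic tree in the mirror-tree score.
#'
#' @param rows named character vector of equal-length aligned sequences
#'   (>= 3 species).
#' @return Symmetric numeric matrix with zero diagonal and species dimnames.
#' @export
identity_distance_matrix <- function(rows) {
  if (length(rows) < 3) abort("need at least 3 species", class = "tcsmeta_data_error")
  rm <- residue_matrix(rows)
  n <- nrow(rm)
  gap <- rm == "-"
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (k in seq_len(n - 1)) {
    for (l in (k + 1):n) {
      ok <- !gap[k, ] & !gap[l, ]
      if (!any(ok)) {
        abort(sprintf("rows %s and %s share no comparable columns",
                      names(rows)[k], names(rows)[l]),
              class = "tcsmeta_data_error")
      }
      d[k, l] <- d[l, k] <- 1 - mean(rm[k, ok] == rm[l, ok])
    }
  }
  d
}

#' Mirror-tree interaction score
#'
#' Interacting proteins tend to have similar phylogenetic histories. The
#' score is the Pearson correlation between the upper triangles of the two
#' proteins' inter-species distance matrices over the common species —
#' "mirror" trees yield correlated distances. Scale-invariant (Pearson) and
#' symmetric in the two proteins.
#'
#' @param pa a [build_paired_alignment()] result with >= 3 common species.
#' @return Correlation in `[-1, 1]`; 0 with attribute `missing_evidence`
#'   when either distance matrix is constant.
#' @export
mirror_tree_score <- function(pa) {
  stopifnot(inherits(pa, "tcs_paired_alignment"))
  if (pa$n_species < 3) abort("need at least 3 common species", class = "tcsmeta_data_error")
  da <- identity_distance_matrix(pa$rows_a)
  db <- identity_distance_matrix(pa$rows_b)
  ua <- da[upper.tri(da)]
  ub <- db[upper.tri(db)]
  if (sd(ua) == 0 || sd(ub) == 0) {
    return(structure(0, missing_evidence = TRUE))
  }
  cor(ua, ub)
}
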