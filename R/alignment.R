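#' Configuration for the genome-context features
#'
#' Collects the cutoffs and alignment parameters shared by the fusion,
#' profile, neighbourhood and operon features.
#'
#' @param evalue_cutoff significance cutoff for local-alignment homology
#'   hits (default `1e-5`).
#' @param mi_cutoff mutual-information cutoff in bits below which a profile
#'   pair counts as no evidence (default 0.35).
#' @param gn_distance_cutoff maximum intergenic gap in bp for gene
#'   neighbourhood evidence (default 200).
#' @param sw_matrix substitution matrix name for local alignments
#'   (default `"BLOSUM62"`).
#' @param sw_gap_open,sw_gap_extend affine gap penalties (defaults 11 and 1).
#' @param ka_lambda,ka_k Karlin-Altschul parameters of the score-to-e-value
#'   model `E = K * m * n * exp(-lambda * S)`; defaults are the standard
#'   gapped BLOSUM62(11,1) constants 0.267 and 0.041.
#' @return A list of class `tcs_context_config`.
#' @export
context_config <- function(evalue_cutoff = 1e-5, mi_cutoff = 0.35,
                           gn_distance_cutoff = 200,
                           sw_matrix = "BLOSUM62",
                           sw_gap_open = 11, sw_gap_extend = 1,
                           ka_lambda = 0.267, ka_k = 0.041) {
  stopifnot(evalue_cutoff > 0, mi_cutoff > 0, gn_distance_cutoff > 0,
            sw_gap_open >= 0, sw_gap_extend > 0, ka_lambda > 0, ka_k > 0)
  structure(
    list(evalue_cutoff = evalue_cutoff, mi_cutoff = mi_cutoff,
         gn_distance_cutoff = gn_distance_cutoff, sw_matrix = sw_matrix,
         sw_gap_open = sw_gap_open, sw_gap_extend = sw_gap_extend,
         ka_lambda = ka_lambda, ka_k = ka_k),
    class = "tcs_context_config"
  )
}

resolve_matrix <- function(matrix) {
  if (is.character(matrix)) similarity_table(matrix) else matrix
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment with affine gap penalties (a gap of
#' length L costs `gap_open + gap_extend * L`), delegated to
#' `Biostrings::pairwiseAlignment`. The score is the optimum over all local
#' alignments and is never negative; the aligned span on each sequence is
#' returned for downstream fusion-span logic.
#'
#' @param a,b amino-acid sequences (character scalars).
#' @param matrix substitution matrix or its name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (defaults 11 and 1).
#' @return A list with `score` and 1-based inclusive spans `start_a`,
#'   `end_a`, `start_b`, `end_b` (all `NA` when the optimal score is 0).
#' @examples
#' smith_waterman("HEAGAWGHEE", "PAWHEAE", matrix = "BLOSUM50",
#'                gap_open = 0, gap_extend = 8)$score
#' @export
smith_waterman <- function(a, b, matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  mat <- resolve_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend
  )
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(list(score = max(sc, 0), start_a = NA_integer_, end_a = NA_integer_,
                start_b = NA_integer_, end_b = NA_integer_))
  }
  list(
    score = sc,
    start_a = Biostrings::start(Biostrings::pattern(pa)),
    end_a = Biostrings::end(Biostrings::pattern(pa)),
    start_b = Biostrings::start(Biostrings::subject(pa)),
    end_b = Biostrings::end(Biostrings::subject(pa))
  )
}

# Vector of local-alignment scores of one query against a set of subject
# sequences (scores only; used for homology scans).
local_scores <- function(query, subjects, cfg) {
  if (length(subjects) == 0) return(numeric(0))
  mat <- resolve_matrix(cfg$sw_matrix)
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(subjects), Biostrings::AAString(query),
    type = "local", substitutionMatrix = mat,
    gapOpening = cfg$sw_gap_open, gapExtension = cfg$sw_gap_extend,
    scoreOnly = TRUE
  )
}

#' Karlin-Altschul e-value of a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length and `n` the
#' total search-space (database) length. This maps raw Smith-Waterman scores
#' onto the e-value scale on which the 1e-5 homology cutoff is defined, so
#' local-alignment scans and external BLAST tabular output are
#' interchangeable presence callers.
#'
#' @param score local alignment score.
#' @param m query length (residues).
#' @param n database length (total residues searched).
#' @param cfg a [context_config()] supplying `ka_lambda` and `ka_k`.
#' @return E-value (>= 0); vectorized over `score`.
#' @export
alignment_evalue <- function(score, m, n, cfg = context_config()) {
  cfg$ka_k * m * n * exp(-cfg$ka_lambda * score)
}

# Minimum score reaching the e-value cutoff in a search space of m x n.
score_cutoff <- function(m, n, cfg) {
  log(cfg$ka_k * m * n / cfg$evalue_cutoff) / cfg$ka_lambda
}
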