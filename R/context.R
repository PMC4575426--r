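#' Phylogenetic presence/absence profile of a protein
#'
#' Scans every reference genome for a significant homolog of the query
#' protein: presence in genome `g` is 1 when the best local-alignment hit in
#' `g`'s proteome reaches the e-value cutoff (see [alignment_evalue()]).
#' Functionally coupled proteins tend to be gained and lost together across
#' genomes, so similar profiles are interaction evidence.
#'
#' @param protein amino-acid sequence of the query.
#' @param genomes a [reference_genome_set()].
#' @param cfg a [context_config()].
#' @return An object of class `tcs_phylo_profile`: list with `presence`
#'   (named 0/1 integer vector over genome ids) and `evalue_cutoff`.
#' @export
build_phylo_profile <- function(protein, genomes, cfg = context_config()) {
  stopifnot(inherits(genomes, "tcs_genome_set"))
  if (length(genomes$genomes) == 0) {
    abort("empty genome set", class = "tcsmeta_data_error")
  }
  presence <- vapply(genomes$genomes, function(g) {
    if (length(g$proteome) == 0) {
      warn(sprintf("genome %s has an empty proteome; presence set to 0", g$genome_id))
      return(0L)
    }
    scores <- local_scores(protein, g$proteome, cfg)
    n_db <- sum(nchar(g$proteome))
    e_best <- min(alignment_evalue(scores, nchar(protein), n_db, cfg))
    as.integer(e_best <= cfg$evalue_cutoff)
  }, integer(1))
  structure(list(presence = presence, evalue_cutoff = cfg$evalue_cutoff),
            class = "tcs_phylo_profile")
}

#' @export
print.tcs_phylo_profile <- function(x, ...) {
  cat(sprintf("<tcs_phylo_profile> present in %d / %d genomes (E <= %g)\n",
              sum(x$presence), length(x$presence), x$evalue_cutoff))
  invisible(x)
}

profile_vec <- function(p) {
  if (inherits(p, "tcs_phylo_profile")) p$presence else p
}

#' Mutual information between two presence/absence profiles in bits
#'
#' `MI = sum over x,y in {0,1} of f(x,y) * log2(f(x,y) / (f(x) f(y)))` with
#' the convention `0 * log 0 = 0`, where `f` are empirical frequencies over
#' the shared genome index. Symmetric and non-negative.
#'
#' @param p,q `tcs_phylo_profile` objects or named 0/1 vectors over the same
#'   genome ids.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(p, q) {
  pv <- profile_vec(p)
  qv <- profile_vec(q)
  if (length(pv) != length(qv) ||
      (!is.null(names(pv)) && !is.null(names(qv)) && !identical(names(pv), names(qv)))) {
    abort("profiles must be indexed by the same genomes", class = "tcsmeta_data_error")
  }
  n <- length(pv)
  mi <- 0
  for (x in 0:1) {
    for (y in 0:1) {
      fxy <- sum(pv == x & qv == y) / n
      if (fxy > 0) {
        mi <- mi + fxy * log2(fxy / ((sum(pv == x) / n) * (sum(qv == y) / n)))
      }
    }
  }
  max(mi, 0)
}

#' Phylogenetic-profile interaction score
#'
#' Mutual information between the two profiles, in bits, clamped to
#' `[0, 1]`, with values below the evidence cutoff (default 0.35 bits)
#' zeroed. The graded value — not a binary flag — is passed downstream so
#' the meta-classifier sees the strength of the profile agreement.
#'
#' @param p,q phylogenetic profiles over the same genome set.
#' @param cfg a [context_config()] supplying `mi_cutoff`.
#' @return Score in `[0, 1]`, or `NA` (missing evidence) when either
#'   profile is constant (all present or all absent), where mutual
#'   information is uninformative.
#' @export
pp_score <- function(p, q, cfg = context_config()) {
  pv <- profile_vec(p)
  qv <- profile_vec(q)
  if (length(unique(pv)) < 2 || length(unique(qv)) < 2) return(NA_real_)
  mi <- min(mutual_information(p, q), 1)
  if (mi < cfg$mi_cutoff) 0 else mi
}

#' Gene-fusion (Rosetta stone) evidence in one genome
#'
#' Evidence that the HK and RR interact because some genome encodes them as
#' one protein: a single protein in the genome must have significant local
#' alignments to *both* query sequences, with the two aligned spans on that
#' protein overlapping by less than 20 % of the shorter span — a genuine
#' two-domain fusion rather than one shared domain matching both queries.
#'
#' @param hk,rr amino-acid sequences of the candidate pair.
#' @param genome a [genome_annotation()].
#' @param cfg a [context_config()].
#' @param max_span_overlap maximum allowed fractional overlap of the two
#'   spans (default 0.2).
#' @return `"evidence"` or `"no-evidence"`.
#' @export
detect_fusion <- function(hk, rr, genome, cfg = context_config(),
                          max_span_overlap = 0.2) {
  stopifnot(inherits(genome, "tcs_genome"))
  if (length(genome$proteome) == 0) return("no-evidence")
  n_db <- sum(nchar(genome$proteome))
  s_hk <- local_scores(hk, genome$proteome, cfg)
  s_rr <- local_scores(rr, genome$proteome, cfg)
  hit_hk <- alignment_evalue(s_hk, nchar(hk), n_db, cfg) <= cfg$evalue_cutoff
  hit_rr <- alignment_evalue(s_rr, nchar(rr), n_db, cfg) <= cfg$evalue_cutoff
  for (i in which(hit_hk & hit_rr)) {
    target <- genome$proteome[[i]]
    span_hk <- smith_waterman(hk, target, cfg$sw_matrix, cfg$sw_gap_open, cfg$sw_gap_extend)
    span_rr <- smith_waterman(rr, target, cfg$sw_matrix, cfg$sw_gap_open, cfg$sw_gap_extend)
    ov <- span_overlap(span_hk$start_b, span_hk$end_b, span_rr$start_b, span_rr$end_b)
    if (!is.na(ov) && ov < max_span_overlap) return("evidence")
  }
  "no-evidence"
}

# Fractional overlap of two 1-based inclusive spans, relative to the
# shorter span.
span_overlap <- function(s1, e1, s2, e2) {
  if (anyNA(c(s1, e1, s2, e2))) return(NA_real_)
  inter <- max(0, min(e1, e2) - max(s1, s2) + 1)
  inter / min(e1 - s1 + 1, e2 - s2 + 1)
}

#' Gene-neighbourhood evidence between two gene records
#'
#' Evidence when the intergenic gap — the number of bases strictly between
#' the upstream gene's end and the downstream gene's start — is at most the
#' cutoff (default 200 bp). Overlapping genes have gap 0 and therefore
#' evidence. Strand-agnostic.
#'
#' @param gene_a,gene_b single-row gene records (with `start`, `end`) from
#'   the same genome.
#' @param cfg a [context_config()] supplying `gn_distance_cutoff`.
#' @return `"evidence"` or `"no-evidence"`.
#' @export
neighbourhood_evidence <- function(gene_a, gene_b, cfg = context_config()) {
  gap <- intergenic_gap(gene_a, gene_b)
  if (gap <= cfg$gn_distance_cutoff) "evidence" else "no-evidence"
}

# Bases strictly between two genes; 0 when they touch or overlap.
intergenic_gap <- function(gene_a, gene_b) {
  up <- if (gene_a$start <= gene_b$start) gene_a else gene_b
  down <- if (gene_a$start <= gene_b$start) gene_b else gene_a
  max(0, down$start - up$end - 1)
}

#' Gene-operon evidence between two gene records
#'
#' Evidence when both genes carry an operon (transcription-unit) assignment
#' and the assignments are equal; a missing assignment on either gene is
#' conservatively no evidence.
#'
#' @param gene_a,gene_b single-row gene records with an `operon_id` field.
#' @return `"evidence"` or `"no-evidence"`.
#' @export
operon_evidence <- function(gene_a, gene_b) {
  oa <- gene_a$operon_id
  ob <- gene_b$operon_id
  if (is.na(oa) || is.na(ob)) return("no-evidence")
  if (oa == ob) "evidence" else "no-evidence"
}

#' 16S rRNA evolutionary distance between two organisms
#'
#' The two sequences are globally aligned and the proportion `p` of
#' differing sites (over columns where neither sequence is gapped) is
#' Jukes-Cantor corrected: `d = -(3/4) * ln(1 - 4p/3)`. Identical sequences
#' give 0; `p >= 0.75` (beyond the correction's domain) saturates at a
#' ceiling of 5. Symmetric.
#'
#' @param a,b 16S rRNA nucleotide sequences.
#' @param saturation_ceiling distance returned when the correction is
#'   undefined (default 5).
#' @return Non-negative distance.
#' @export
evolutionary_distance_16s <- function(a, b, saturation_ceiling = 5) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  if (identical(a, b)) return(0)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 5, gapExtension = 2
  )
  ca <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  cb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ok <- ca != "-" & cb != "-"
  if (!any(ok)) return(saturation_ceiling)
  p <- mean(ca[ok] != cb[ok])
  if (p >= 0.75) return(saturation_ceiling)
  -(3 / 4) * log(1 - 4 * p / 3)
}

#' Aggregate per-genome context evidence into one score
#'
#' Weighted fraction of evaluable genomes showing evidence:
#' `sum(w_g * [evidence_g]) / sum(w_g)` over evaluable genomes, with
#' `w_g = 1 / (1 + d_g)` from the genome set's 16S distances. Genomes marked
#' `"not-evaluable"` (e.g. an ortholog absent) are excluded from both sums.
#' Monotone: adding an evidence genome never lowers the score, adding a
#' no-evidence genome never raises it.
#'
#' @param evidence named character vector over genome ids with values
#'   `"evidence"`, `"no-evidence"` or `"not-evaluable"`.
#' @param genomes a [reference_genome_set()] supplying the weights.
#' @return Score in `[0, 1]`, or `NA` when no genome is evaluable.
#' @export
aggregate_context_score <- function(evidence, genomes) {
  stopifnot(inherits(genomes, "tcs_genome_set"))
  if (is.null(names(evidence)) || !all(names(evidence) %in% names(genomes$weights))) {
    abort("evidence must be named by genome ids from the genome set",
          class = "tcsmeta_data_error")
  }
  ok <- evidence != "not-evaluable"
  if (!any(ok)) return(NA_real_)
  w <- genomes$weights[names(evidence)[ok]]
  sum(w * (evidence[ok] == "evidence")) / sum(w)
}

# Best significant hit of a query in one genome's proteome; NA when no hit
# reaches the e-value cutoff. With reciprocal = TRUE the hit must also map
# back to the query among `home_proteome` (reciprocal best hit).
find_ortholog <- function(query, genome, cfg = context_config(),
                          home_proteome = NULL, query_id = NULL) {
  if (length(genome$proteome) == 0) return(NA_character_)
  scores <- local_scores(query, genome$proteome, cfg)
  n_db <- sum(nchar(genome$proteome))
  ev <- alignment_evalue(scores, nchar(query), n_db, cfg)
  if (min(ev) > cfg$evalue_cutoff) return(NA_character_)
  best <- names(genome$proteome)[which.max(scores)]
  if (!is.null(home_proteome) && !is.null(query_id)) {
    back <- local_scores(genome$proteome[[best]], home_proteome, cfg)
    if (names(home_proteome)[which.max(back)] != query_id) return(NA_character_)
  }
  best
}

# Shared scaffold of the GN/GO aggregate scores: resolve both orthologs per
# genome, apply the per-genome evidence rule, aggregate with 16S weights.
context_pair_score <- function(hk, rr, genomes, cfg, rule) {
  evidence <- vapply(genomes$genomes, function(g) {
    o_hk <- find_ortholog(hk, g, cfg)
    o_rr <- find_ortholog(rr, g, cfg)
    if (is.na(o_hk) || is.na(o_rr) || o_hk == o_rr) return("not-evaluable")
    ga <- g$genes[g$genes$gene_id == o_hk, ]
    gb <- g$genes[g$genes$gene_id == o_rr, ]
    if (nrow(ga) == 0 || nrow(gb) == 0) return("not-evaluable")
    rule(ga, gb)
  }, character(1))
  aggregate_context_score(evidence, genomes)
}

#' Aggregate gene-neighbourhood score for a candidate pair
#'
#' Resolves orthologs of both proteins in every reference genome and applies
#' [neighbourhood_evidence()] where both are found, aggregating with
#' [aggregate_context_score()].
#'
#' @param hk,rr amino-acid sequences of the pair.
#' @param genomes a [reference_genome_set()].
#' @param cfg a [context_config()].
#' @return Score in `[0, 1]`, or `NA` when no genome is evaluable.
#' @export
gn_score <- function(hk, rr, genomes, cfg = context_config()) {
  context_pair_score(hk, rr, genomes, cfg,
                     function(ga, gb) neighbourhood_evidence(ga, gb, cfg))
}

#' Aggregate gene-operon score for a candidate pair
#'
#' As [gn_score()] but per-genome evidence is shared operon membership
#' ([operon_evidence()]).
#'
#' @inheritParams gn_score
#' @return Score in `[0, 1]`, or `NA` when no genome is evaluable.
#' @export
go_score <- function(hk, rr, genomes, cfg = context_config()) {
  context_pair_score(hk, rr, genomes, cfg, operon_evidence)
}

#' Aggregate gene-fusion score for a candidate pair
#'
#' Applies [detect_fusion()] in every reference genome and aggregates the
#' per-genome evidence with [aggregate_context_score()]. Every genome with a
#' non-empty proteome is evaluable for fusion.
#'
#' @inheritParams gn_score
#' @return Score in `[0, 1]`, or `NA` when no genome is evaluable.
#' @export
gf_score <- function(hk, rr, genomes, cfg = context_config()) {
  evidence <- vapply(genomes$genomes, function(g) {
    if (length(g$proteome) == 0) return("not-evaluable")
    detect_fusion(hk, rr, g, cfg)
  }, character(1))
  aggregate_context_score(evidence, genomes)
}
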