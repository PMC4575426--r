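#' Compute the six-feature table for a directory of inputs
#'
#' Runs the whole feature stage over a directory laid out as
#' [simulate_fixture_dir()] writes it: `pairs.csv`, per-protein aligned
#' FASTA MSAs under `msa/` (`<protein_id>.afa`), a genome bundle under
#' `genomes/`, and per-pair protein sequences in `proteins.faa`. The
#' coevolution features come from the pair's MSAs (missing when either MSA
#' is absent or the species overlap is insufficient); the genome-context
#' features come from the pair's protein sequences scanned against the
#' bundle (missing when a sequence is absent). Deterministic: identical
#' inputs give an identical table.
#'
#' @param dir input directory.
#' @param cfg a [context_config()].
#' @param min_species,max_species species-overlap bounds for the paired
#'   alignments (defaults 25 and 50).
#' @return A feature table tibble (one row per predictable pair), as
#'   [feature_table()] returns.
#' @export
directory_feature_table <- function(dir, cfg = context_config(),
                                    min_species = 25, max_species = 50) {
  pairs <- load_pair_dataset(file.path(dir, "pairs.csv"))
  genomes <- read_genome_bundle(file.path(dir, "genomes"))
  prot_path <- file.path(dir, "proteins.faa")
  proteins <- character(0)
  if (file.exists(prot_path)) {
    aa <- Biostrings::readAAStringSet(prot_path)
    proteins <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  }
  msa_path <- function(id) file.path(dir, "msa", paste0(id, ".afa"))

  scorer_factory <- function(row) {
    pa <- NULL
    if (file.exists(msa_path(row$hk_id)) && file.exists(msa_path(row$rr_id))) {
      pa <- tryCatch(
        build_paired_alignment(read_msa(msa_path(row$hk_id)),
                               read_msa(msa_path(row$rr_id)),
                               min_species = min_species,
                               max_species = max_species),
        tcsmeta_insufficient_overlap = function(e) NULL
      )
    }
    hk_seq <- proteins[[row$hk_id]] %||% NULL
    rr_seq <- proteins[[row$rr_id]] %||% NULL
    ctx <- function(f) {
      if (is.null(hk_seq) || is.null(rr_seq)) return(function() NA_real_)
      function() f(hk_seq, rr_seq, genomes, cfg)
    }
    list(
      i2h = function() if (is.null(pa)) NA_real_ else i2h_score(pa),
      mt = function() if (is.null(pa)) NA_real_ else mirror_tree_score(pa),
      gf = ctx(gf_score),
      pp = if (is.null(hk_seq) || is.null(rr_seq)) {
        function() NA_real_
      } else {
        function() pp_score(build_phylo_profile(hk_seq, genomes, cfg),
                            build_phylo_profile(rr_seq, genomes, cfg), cfg)
      },
      gn = ctx(gn_score),
      go = ctx(go_score)
    )
  }
  feature_table(pairs, scorer_factory)
}
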