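#' Simulate a pair of co-evolving multiple sequence alignments
#'
#' Generates two alignments over the same species with a tunable fraction of
#' co-evolving column pairs. Each column follows a categorical substitution
#' process: species carry a latent state (one of `n_states`), the column's
#' residue is a column-specific mapping of that state, and a `noise`
#' fraction of residues is randomized. For a *coupled* column pair (column
#' `j` of protein A with column `j` of protein B) the two columns share one
#' latent-state vector, so they mutate in lock-step across species —
#' detectable covariation without any claim to realistic tree shapes. The
#' remaining columns draw independent latent vectors. Deterministic given
#' `seed`.
#'
#' @param n_species number of species (>= 3; default 30).
#' @param msa_length alignment columns per protein (default 150).
#' @param coupling fraction of column pairs that co-evolve, in `[0, 1]`.
#' @param n_states latent states per column (default 4).
#' @param noise per-residue randomization probability (default 0.05).
#' @param seed integer seed.
#' @return A list with [tcs_msa()] elements `msa_a`, `msa_b` over identical
#'   species, and `coupled_columns` (indices of the planted pairs).
#' @export
simulate_coevolving_msas <- function(n_species = 30, msa_length = 150,
                                     coupling = 0.5, n_states = 4,
                                     noise = 0.05, seed = 1) {
  stopifnot(n_species >= 3, msa_length >= 1)
  if (coupling < 0 || coupling > 1) {
    abort("coupling must lie in [0, 1]", class = "tcsmeta_data_error")
  }
  species <- sprintf("sp%03d", seq_len(n_species))
  n_coupled <- round(coupling * msa_length)
  rng_with_seed(seed, {
    draw_column <- function(latent, residues) {
      col <- residues[latent]
      flip <- runif(n_species) < noise
      col[flip] <- sample(AA20, sum(flip), replace = TRUE)
      col
    }
    cols_a <- matrix("", n_species, msa_length)
    cols_b <- matrix("", n_species, msa_length)
    for (j in seq_len(msa_length)) {
      latent_a <- sample.int(n_states, n_species, replace = TRUE)
      res_a <- sample(AA20, n_states)
      if (j <= n_coupled) {
        # lock-step: one substitution process drives both columns
        latent_b <- latent_a
        res_b <- res_a
      } else {
        latent_b <- sample.int(n_states, n_species, replace = TRUE)
        res_b <- sample(AA20, n_states)
      }
      cols_a[, j] <- draw_column(latent_a, res_a)
      cols_b[, j] <- draw_column(latent_b, res_b)
    }
  })
  rows_a <- setNames(apply(cols_a, 1, paste, collapse = ""), species)
  rows_b <- setNames(apply(cols_b, 1, paste, collapse = ""), species)
  list(
    msa_a = tcs_msa(rows_a, query_id = "hk_sim"),
    msa_b = tcs_msa(rows_b, query_id = "rr_sim"),
    coupled_columns = seq_len(n_coupled)
  )
}

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE), collapse = "")

mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  flip <- runif(length(chars)) < rate
  chars[flip] <- sample(AA20, sum(flip), replace = TRUE)
  paste(chars, collapse = "")
}

mutate_dna <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  flip <- runif(length(chars)) < rate
  chars[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
  paste(chars, collapse = "")
}

#' Simulate a reference genome set with planted context events
#'
#' Builds `n_genomes` genomes of random background proteins plus a focal
#' HK/RR pair, planting exactly the events requested: *fusion* (the genome
#' carries the HK and RR concatenated as one protein), *neighbour* (HK and
#' RR orthologs with a specified intergenic gap), *operon* (adjacent
#' orthologs sharing an operon id), and per-genome *presence* patterns for
#' the phylogenetic profiles. When both orthologs are present without a
#' neighbour/operon plant they are placed far apart with background genes
#' between them. Background genes sit in singleton operons separated by
#' gaps well above the neighbourhood cutoff, so no spurious context
#' evidence arises. Each genome receives a 16S sequence mutated from a
#' common ancestor so distance weights differ across genomes.
#'
#' An operon plant requires both orthologs in that genome; requesting one
#' where either protein is absent is a contradictory plant and errors.
#'
#' @param n_genomes number of reference genomes (>= 2; default 8).
#' @param fusion_genomes integer indices of genomes carrying the fused
#'   protein.
#' @param neighbour_genomes indices with the HK/RR orthologs planted at
#'   `neighbour_gap`.
#' @param neighbour_gap intergenic gap in bp for neighbour plants
#'   (default 150).
#' @param operon_genomes indices where the orthologs share an operon.
#' @param hk_presence,rr_presence logical vectors (length `n_genomes`)
#'   giving the planted presence patterns; default all `TRUE`.
#' @param n_background background proteins per genome (default 6).
#' @param ortholog_mutation per-residue mutation rate applied to planted
#'   orthologs (default 0: verbatim copies).
#' @param seed integer seed.
#' @return A list with `genomes` (a [reference_genome_set()]), the focal
#'   sequences `hk`, `rr`, and `truth` — a tibble per genome with the
#'   planted fusion/neighbour/operon flags and effective presence (fusion
#'   implies presence of both, since the fused protein is a significant hit
#'   for each query).
#' @export
simulate_reference_genomes <- function(n_genomes = 8,
                                       fusion_genomes = integer(0),
                                       neighbour_genomes = integer(0),
                                       neighbour_gap = 150,
                                       operon_genomes = integer(0),
                                       hk_presence = NULL, rr_presence = NULL,
                                       n_background = 6,
                                       ortholog_mutation = 0,
                                       seed = 1) {
  stopifnot(n_genomes >= 2)
  hk_presence <- hk_presence %||% rep(TRUE, n_genomes)
  rr_presence <- rr_presence %||% rep(TRUE, n_genomes)
  stopifnot(length(hk_presence) == n_genomes, length(rr_presence) == n_genomes)
  for (g in union(neighbour_genomes, operon_genomes)) {
    if (!hk_presence[g] || !rr_presence[g]) {
      abort(sprintf("contradictory plant: genome %d lacks a protein required by a neighbour/operon plant", g),
            class = "tcsmeta_data_error")
    }
  }
  rng_with_seed(seed, {
    hk <- random_protein(150)
    rr <- random_protein(120)
    ancestor_16s <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE), collapse = "")
    genomes <- lapply(seq_len(n_genomes), function(g) {
      gid <- sprintf("genome%02d", g)
      proteins <- setNames(
        vapply(seq_len(n_background), function(i) random_protein(sample(90:140, 1)), character(1)),
        sprintf("%s_bg%02d", gid, seq_len(n_background))
      )
      linked <- g %in% neighbour_genomes || g %in% operon_genomes
      if (hk_presence[g]) proteins[[paste0(gid, "_hk")]] <- mutate_protein(hk, ortholog_mutation)
      if (rr_presence[g]) proteins[[paste0(gid, "_rr")]] <- mutate_protein(rr, ortholog_mutation)
      if (g %in% fusion_genomes) proteins[[paste0(gid, "_fus")]] <- paste0(hk, rr)
      # gene order: hk first, background block, then rr — unless linked,
      # in which case hk and rr are consecutive at the planted gap
      ids <- names(proteins)
      bg_ids <- grep("_bg", ids, value = TRUE)
      order_ids <- if (linked) {
        c(paste0(gid, "_hk"), paste0(gid, "_rr"), bg_ids, grep("_fus", ids, value = TRUE))
      } else {
        c(intersect(paste0(gid, "_hk"), ids), bg_ids,
          intersect(paste0(gid, "_rr"), ids), grep("_fus", ids, value = TRUE))
      }
      order_ids <- order_ids[order_ids %in% ids]
      pos <- 1
      rows <- vector("list", length(order_ids))
      for (i in seq_along(order_ids)) {
        id <- order_ids[i]
        len_nt <- nchar(proteins[[id]]) * 3 + 3
        start <- pos
        end <- pos + len_nt - 1
        gap_after <- if (linked && i == 1) neighbour_gap else sample(400:900, 1)
        pos <- end + gap_after + 1
        operon <- if (g %in% operon_genomes && id %in% paste0(gid, c("_hk", "_rr"))) {
          paste0(gid, "_op_tcs")
        } else {
          paste0(gid, "_op_", id)
        }
        rows[[i]] <- tibble(gene_id = id, start = start, end = end,
                            strand = "+", operon_id = operon)
      }
      genome_annotation(gid, bind_rows(rows), proteins,
                        rrna_16s = mutate_dna(ancestor_16s, stats::runif(1, 0.01, 0.10)))
    })
  })
  gs <- reference_genome_set(genomes, target_16s = genomes[[1]]$rrna_16s)
  truth <- tibble(
    genome_id = sprintf("genome%02d", seq_len(n_genomes)),
    fusion = seq_len(n_genomes) %in% fusion_genomes,
    neighbour = seq_len(n_genomes) %in% neighbour_genomes,
    operon = seq_len(n_genomes) %in% operon_genomes,
    hk_present = hk_presence | .data$fusion,
    rr_present = rr_presence | .data$fusion
  )
  list(genomes = gs, hk = hk, rr = rr, truth = truth)
}

#' Simulate a labelled six-feature table
#'
#' Draws six-dimensional Gaussian feature vectors (noise sd 1) and shifts
#' the interacting class by `class_separation` scaled per feature by
#' `informative` — by default the i2h slot carries the strongest signal,
#' the mirror-tree slot half of it, and the four genome-context slots a
#' quarter, mimicking the relative usefulness of the six methods. The
#' default class sizes reproduce the 113:1134 imbalance of the curated
#' gold-standard sets.
#'
#' @param n_positive,n_negative class sizes (defaults 113 and 1134).
#' @param class_separation effect size in noise-sd units (default 2).
#' @param informative named per-feature multipliers of the shift.
#' @param seed integer seed.
#' @return A tibble with `label` and the six feature columns.
#' @export
simulate_feature_table <- function(n_positive = 113, n_negative = 1134,
                                   class_separation = 2,
                                   informative = c(i2h = 1, mt = 0.5, gf = 0.25,
                                                   pp = 0.25, gn = 0.25, go = 0.25),
                                   seed = 1) {
  stopifnot(n_positive >= 1, n_negative >= 1)
  stopifnot(all(FEATURE_ORDER %in% names(informative)))
  n <- n_positive + n_negative
  rng_with_seed(seed, {
    X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, FEATURE_ORDER))
    shift <- class_separation * informative[FEATURE_ORDER]
    X[seq_len(n_positive), ] <- X[seq_len(n_positive), ] +
      matrix(shift, n_positive, 6, byrow = TRUE)
  })
  out <- as_tibble(X)
  out$label <- c(rep("interacting", n_positive), rep("non-interacting", n_negative))
  out[, c("label", FEATURE_ORDER)]
}

#' Synthetic stand-in for the curated gold-standard pair sets
#'
#' Builds a pair dataset with the structure of the curated two-component
#' benchmark: 113 interacting and 1134 non-interacting pairs, the positives
#' splitting into 56 neighbouring (genes consecutive on the chromosome) and
#' 57 orphan pairs, distributed over six species with the benchmark's
#' per-species interacting:non-interacting ratios (Escherichia coli 22:64,
#' Myxococcus xanthus 20:216, Synechocystis sp. 20:319, Mesorhizobium loti
#' 20:364, Caulobacter crescentus 16:5, remainder 15:166). All identifiers
#' and genomic layouts are synthetic; only the set structure mirrors the
#' curated benchmark.
#'
#' @param n_neighbouring number of positives planted as consecutive gene
#'   pairs (default 56; the remaining positives are orphans).
#' @param seed integer seed for the genomic layout.
#' @return A list with `pairs` (a [tcs_pairs()] tibble carrying an
#'   `adjacent` column) and `annotations` (named list of
#'   [genome_annotation()] objects, one per species, in which neighbouring
#'   pairs are consecutive genes and orphan pairs are separated by a spacer
#'   gene).
#' @export
synthetic_gold_standard <- function(n_neighbouring = 56, seed = 2015) {
  comp <- tibble(
    species = c("Escherichia coli", "Myxococcus xanthus", "Synechocystis sp.",
                "Mesorhizobium loti", "Caulobacter crescentus", "Other species"),
    tag = c("eco", "mxa", "syn", "mlo", "ccr", "oth"),
    n_pos = c(22, 20, 20, 20, 16, 15),
    n_neg = c(64, 216, 319, 364, 5, 166)
  )
  pairs <- bind_rows(lapply(seq_len(nrow(comp)), function(i) {
    with(comp[i, ], bind_rows(
      tibble(hk_id = sprintf("%s_hk%03d", tag, seq_len(n_pos)),
             rr_id = sprintf("%s_rr%03d", tag, seq_len(n_pos)),
             label = "interacting", species = species),
      tibble(hk_id = sprintf("%s_hk%03d", tag, rep_len(seq_len(n_pos), n_neg)),
             rr_id = sprintf("%s_rr%03d", tag, n_pos + seq_len(n_neg)),
             label = "non-interacting", species = species)
    ))
  }))
  pos_idx <- which(pairs$label == "interacting")
  pairs$adjacent <- FALSE
  pairs$adjacent[pos_idx[seq_len(n_neighbouring)]] <- TRUE

  annotations <- lapply(split(pairs, pairs$species), function(sp) {
    genes <- list()
    pos <- 1
    add_gene <- function(id) {
      if (id %in% vapply(genes, function(g) g$gene_id, character(1))) return(invisible())
      len <- 900
      genes[[length(genes) + 1]] <<- tibble(
        gene_id = id, start = pos, end = pos + len - 1,
        strand = "+", operon_id = NA_character_)
      pos <<- pos + len + 500
    }
    for (i in seq_len(nrow(sp))) {
      add_gene(sp$hk_id[i])
      if (!sp$adjacent[i]) add_gene(sprintf("%s_spacer%04d", sp$species[1], i))
      add_gene(sp$rr_id[i])
    }
    genome_annotation(sp$species[1], bind_rows(genes))
  })
  list(pairs = tcs_pairs(pairs, provenance = "synthetic gold-standard stand-in"),
       annotations = annotations)
}

#' Write a complete synthetic fixture directory
#'
#' Emits everything a pipeline run needs: a pair CSV, co-evolving MSAs for
#' every interacting pair (and uncoupled MSAs for non-interacting pairs), a
#' genome bundle with planted context events, and a `truth.json` recording
#' the planted structure. All files are plain text.
#'
#' @param dir output directory.
#' @param n_pairs_pos,n_pairs_neg numbers of interacting / non-interacting
#'   pairs (kept small; fixtures are for testing, not benchmarking).
#' @param n_species,msa_length,coupling passed to
#'   [simulate_coevolving_msas()]; `coupling` applies to interacting pairs,
#'   non-interacting pairs get coupling 0.
#' @param n_genomes passed to [simulate_reference_genomes()].
#' @param seed integer seed.
#' @return `dir`, invisibly.
#' @export
simulate_fixture_dir <- function(dir, n_pairs_pos = 3, n_pairs_neg = 5,
                                 n_species = 30, msa_length = 60,
                                 coupling = 0.8, n_genomes = 6, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  msa_dir <- file.path(dir, "msa")
  dir.create(msa_dir, showWarnings = FALSE)
  n <- n_pairs_pos + n_pairs_neg
  pairs <- tibble(
    hk_id = sprintf("hk%03d", seq_len(n)),
    rr_id = sprintf("rr%03d", seq_len(n)),
    label = c(rep("interacting", n_pairs_pos), rep("non-interacting", n_pairs_neg)),
    species = "Synthetic organism"
  )
  write_pair_dataset(pairs, file.path(dir, "pairs.csv"))
  for (i in seq_len(n)) {
    cp <- if (pairs$label[i] == "interacting") coupling else 0
    sim <- simulate_coevolving_msas(n_species = n_species, msa_length = msa_length,
                                    coupling = cp, seed = seed + i)
    write_msa(sim$msa_a, file.path(msa_dir, paste0(pairs$hk_id[i], ".afa")))
    write_msa(sim$msa_b, file.path(msa_dir, paste0(pairs$rr_id[i], ".afa")))
  }
  ref <- simulate_reference_genomes(
    n_genomes = n_genomes,
    fusion_genomes = 1,
    neighbour_genomes = c(2, 3),
    operon_genomes = 3,
    seed = seed
  )
  write_genome_bundle(ref$genomes, file.path(dir, "genomes"))
  # per-pair protein sequences for the genome-context features: interacting
  # pairs carry lightly mutated copies of the focal HK/RR (whose context
  # events are planted in the bundle), negatives get unrelated proteins
  prot_lines <- rng_with_seed(seed + 10000L, {
    unlist(lapply(seq_len(n), function(i) {
      if (pairs$label[i] == "interacting") {
        c(paste0(">", pairs$hk_id[i]), mutate_protein(ref$hk, 0.02),
          paste0(">", pairs$rr_id[i]), mutate_protein(ref$rr, 0.02))
      } else {
        c(paste0(">", pairs$hk_id[i]), random_protein(150),
          paste0(">", pairs$rr_id[i]), random_protein(120))
      }
    }))
  })
  writeLines(prot_lines, file.path(dir, "proteins.faa"))
  jsonlite::write_json(
    list(seed = seed, coupling = coupling, truth = ref$truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
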