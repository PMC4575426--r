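cfg <- context_config()

test_that("phylogenetic profiles recover planted presence patterns exactly", {
  present <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  ref <- simulate_reference_genomes(n_genomes = 8, hk_presence = present,
                                    rr_presence = rep(TRUE, 8), seed = 31)
  prof <- build_phylo_profile(ref$hk, ref$genomes, cfg)
  expect_equal(unname(prof$presence), as.integer(present))

  # unrelated random protein: no significant hit anywhere
  set.seed(99)
  decoy <- paste(sample(rownames(similarity_table()), 130, replace = TRUE),
                 collapse = "")
  decoy_prof <- build_phylo_profile(decoy, ref$genomes, cfg)
  expect_equal(sum(decoy_prof$presence), 0)
})

test_that("empty genome sets error and empty proteomes warn with presence 0", {
  expect_error(reference_genome_set(list()), "length")
  bare <- genome_annotation("empty", tibble::tibble(
    gene_id = "g1", start = 1, end = 10, strand = "+"))
  gs <- reference_genome_set(list(bare))
  expect_warning(prof <- build_phylo_profile("MKTAYIAKQRMKTAYIAKQR", gs, cfg),
                 "empty proteome")
  expect_equal(sum(prof$presence), 0)
})

test_that("mutual information matches the direct four-term sum", {
  expect_equal(mutual_information(c(1, 1, 0, 0, 1, 1, 0, 0),
                                  c(1, 1, 0, 0, 1, 1, 0, 0)), 1.0)
  expect_equal(mutual_information(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.0)

  p <- c(1, 1, 1, 0)
  q <- c(1, 1, 0, 1)
  expect_equal(mutual_information(p, q), mi_sum_oracle(p, q))

  set.seed(17)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    p <- rbinom(n, 1, 0.5)
    q <- rbinom(n, 1, 0.5)
    expect_equal(mutual_information(p, q), mi_sum_oracle(p, q))
    expect_equal(mutual_information(p, q), mutual_information(q, p))
    h <- function(x) {
      f <- mean(x)
      if (f %in% c(0, 1)) 0 else -f * log2(f) - (1 - f) * log2(1 - f)
    }
    expect_lte(mutual_information(p, q), min(h(p), h(q)) + 1e-12)
  }

  expect_error(mutual_information(c(1, 0), c(1, 0, 1)), class = "tcsmeta_data_error")
})

test_that("profile scores clamp mutual information and zero sub-cutoff values", {
  # identical balanced profiles: 1 bit, clamped value 1
  bal <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(pp_score(bal, bal, cfg), 1.0)

  set.seed(23)
  for (i in 1:20) {
    p <- rbinom(10, 1, 0.5)
    q <- rbinom(10, 1, 0.5)
    if (length(unique(p)) < 2 || length(unique(q)) < 2) next
    mi <- mi_sum_oracle(p, q)
    expected <- if (min(mi, 1) < 0.35) 0 else min(mi, 1)
    expect_equal(pp_score(p, q, cfg), expected)
  }

  expect_true(is.na(pp_score(rep(1, 8), bal, cfg)))
})

test_that("fusion detection needs one protein matching both queries on distinct spans", {
  ref <- simulate_reference_genomes(n_genomes = 6, fusion_genomes = c(2, 5), seed = 41)
  calls <- vapply(ref$genomes$genomes,
                  function(g) detect_fusion(ref$hk, ref$rr, g, cfg), character(1))
  expect_equal(unname(calls == "evidence"), ref$truth$fusion)

  # a genome matching the HK twice but never the RR gives no evidence
  genes <- tibble::tibble(gene_id = c("c1", "c2"), start = c(1, 2000),
                          end = c(500, 2500), strand = "+")
  hk_only <- genome_annotation("hkonly", genes,
                               setNames(c(ref$hk, ref$hk), c("c1", "c2")))
  expect_equal(detect_fusion(ref$hk, ref$rr, hk_only, cfg), "no-evidence")
})

test_that("neighbourhood evidence applies the 200-bp intergenic cutoff", {
  gene_at <- function(start, end) tibble::tibble(gene_id = "g", start = start,
                                                 end = end, strand = "+",
                                                 operon_id = NA_character_)
  up <- gene_at(1, 900)
  expect_equal(neighbourhood_evidence(up, gene_at(1051, 1800), cfg), "evidence")    # gap 150
  expect_equal(neighbourhood_evidence(up, gene_at(1101, 1800), cfg), "evidence")    # gap 200
  expect_equal(neighbourhood_evidence(up, gene_at(1102, 1800), cfg), "no-evidence") # gap 201
  expect_equal(neighbourhood_evidence(up, gene_at(800, 1500), cfg), "evidence")     # overlap
})

test_that("operon evidence requires matching assignments on both genes", {
  g <- function(op) tibble::tibble(gene_id = "g", start = 1, end = 10,
                                   strand = "+", operon_id = op)
  expect_equal(operon_evidence(g("op1"), g("op1")), "evidence")
  expect_equal(operon_evidence(g("op1"), g("op2")), "no-evidence")
  expect_equal(operon_evidence(g(NA_character_), g("op1")), "no-evidence")
})

test_that("16S distances follow the Jukes-Cantor closed form", {
  set.seed(51)
  base <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  expect_equal(evolutionary_distance_16s(base, base), 0)

  # mutate exactly 10% of sites to a different base: p-distance 0.10
  chars <- strsplit(base, "")[[1]]
  flip <- sample(400, 40)
  chars[flip] <- vapply(chars[flip], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  mutated <- paste(chars, collapse = "")
  expect_equal(evolutionary_distance_16s(base, mutated),
               -(3 / 4) * log(1 - 4 * 0.10 / 3), tolerance = 1e-6)
  expect_equal(evolutionary_distance_16s(base, mutated),
               evolutionary_distance_16s(mutated, base))
})

test_that("16S Jukes-Cantor agrees with an independent phylogenetics implementation", {
  skip_if_not_installed("ape")
  set.seed(52)
  base <- sample(c("a", "c", "g", "t"), 300, replace = TRUE)
  other <- base
  flip <- sample(300, 24)
  other[flip] <- vapply(other[flip], function(x)
    sample(setdiff(c("a", "c", "g", "t"), x), 1), character(1))
  bin <- ape::as.DNAbin(rbind(one = base, two = other))
  expect_equal(
    evolutionary_distance_16s(toupper(paste(base, collapse = "")),
                              toupper(paste(other, collapse = ""))),
    as.numeric(ape::dist.dna(bin, model = "JC69")),
    tolerance = 1e-8
  )
})

test_that("context aggregation is the 16S-weighted evidence fraction", {
  mk_genome <- function(id) genome_annotation(id, tibble::tibble(
    gene_id = paste0(id, "_g"), start = 1, end = 10, strand = "+"))
  gs <- reference_genome_set(list(mk_genome("g1"), mk_genome("g2"), mk_genome("g3")),
                             distances = c(g1 = 0, g2 = 1, g3 = 3))
  expect_equal(unname(gs$weights), c(1, 0.5, 0.25))

  ev <- c(g1 = "evidence", g2 = "no-evidence", g3 = "no-evidence")
  expect_equal(aggregate_context_score(ev, gs), 1 / 1.75)

  all_ev <- setNames(rep("evidence", 3), paste0("g", 1:3))
  expect_equal(aggregate_context_score(all_ev, gs), 1.0)
  none <- setNames(rep("no-evidence", 3), paste0("g", 1:3))
  expect_equal(aggregate_context_score(none, gs), 0.0)
  expect_true(is.na(aggregate_context_score(
    setNames(rep("not-evaluable", 3), paste0("g", 1:3)), gs)))
})

test_that("aggregation is monotone in added evidence", {
  set.seed(61)
  ids <- sprintf("g%02d", 1:10)
  mk_genome <- function(id) genome_annotation(id, tibble::tibble(
    gene_id = paste0(id, "_g"), start = 1, end = 10, strand = "+"))
  gs <- reference_genome_set(lapply(ids, mk_genome),
                             distances = setNames(runif(10, 0, 2), ids))
  for (i in 1:10) {
    ev <- setNames(sample(c("evidence", "no-evidence", "not-evaluable"),
                          10, replace = TRUE), ids)
    base_score <- aggregate_context_score(ev, gs)
    flips <- which(ev == "not-evaluable")
    if (length(flips) == 0 || is.na(base_score)) next
    ev_up <- ev
    ev_up[flips[1]] <- "evidence"
    expect_gte(aggregate_context_score(ev_up, gs), base_score)
    ev_down <- ev
    ev_down[flips[1]] <- "no-evidence"
    expect_lte(aggregate_context_score(ev_down, gs), base_score)
  }
})

test_that("neighbourhood and operon aggregate scores recover planted genomes", {
  ref <- simulate_reference_genomes(n_genomes = 6, neighbour_genomes = c(1, 4),
                                    operon_genomes = 4, seed = 71)
  w <- ref$genomes$weights
  expect_equal(gn_score(ref$hk, ref$rr, ref$genomes, cfg),
               sum(w[c(1, 4)]) / sum(w))
  expect_equal(go_score(ref$hk, ref$rr, ref$genomes, cfg),
               w[[4]] / sum(w))

  bare <- simulate_reference_genomes(n_genomes = 4, seed = 72)
  expect_equal(gn_score(bare$hk, bare$rr, bare$genomes, cfg), 0)
  expect_equal(go_score(bare$hk, bare$rr, bare$genomes, cfg), 0)
  expect_equal(gf_score(bare$hk, bare$rr, bare$genomes, cfg), 0)
})
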