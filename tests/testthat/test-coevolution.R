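test_that("column similarity vectors match an exhaustive pairwise loop", {
  mat <- similarity_table()
  rows <- c(s1 = "ARND", s2 = "AAAA", s3 = "A-CD", s4 = "AKND")

  # constant column: every entry is the same identical-residue similarity
  v1 <- column_similarity_vector(rows, 1, mat)
  expect_length(v1, 6)
  expect_true(all(v1 == mat["A", "A"]))

  # gap in one of four rows knocks out the 3 pairs involving it
  v2 <- column_similarity_vector(rows, 2, mat)
  expect_equal(sum(is.na(v2)), 3)

  set.seed(1)
  rand_rows <- setNames(
    vapply(1:6, function(i) paste(sample(c(rownames(mat), "-"), 8, replace = TRUE),
                                  collapse = ""), character(1)),
    paste0("sp", 1:6))
  for (col in 1:8) {
    got <- column_similarity_vector(rand_rows, col, mat)
    res <- substr(rand_rows, col, col)
    expected <- c()
    for (k in 1:5) for (l in (k + 1):6) {
      expected <- c(expected,
                    if (res[k] == "-" || res[l] == "-") NA_real_
                    else mat[res[k], res[l]])
    }
    expect_equal(got, expected)
  }
})

test_that("position-pair correlation handles self, anti and degenerate cases", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 2, 4)
  expect_equal(position_pair_correlation(v, v), 1.0)
  expect_equal(position_pair_correlation(v, -v), -1.0)
  expect_equal(position_pair_correlation(rep(1, 12), v), 0)
  # fewer than 10 shared entries is 0 by convention
  short <- c(1:5, rep(NA, 7))
  expect_equal(position_pair_correlation(short, short), 0)
})

test_that("i2h approaches the planted coupled fraction under full coupling", {
  sim <- simulate_coevolving_msas(n_species = 30, msa_length = 40,
                                  coupling = 1, noise = 0, seed = 21)
  pa <- build_paired_alignment(sim$msa_a, sim$msa_b)
  planted_fraction <- 40 / (40 * 40)
  expect_equal(i2h_score(pa), planted_fraction, tolerance = 0.25)
})

test_that("i2h is symmetric in the proteins and invariant to row order", {
  sim <- simulate_coevolving_msas(n_species = 26, msa_length = 30,
                                  coupling = 0.5, seed = 8)
  pa <- build_paired_alignment(sim$msa_a, sim$msa_b)
  swapped <- structure(list(species_list = pa$species_list,
                            rows_a = pa$rows_b, rows_b = pa$rows_a,
                            n_species = pa$n_species),
                       class = "tcs_paired_alignment")
  expect_equal(i2h_score(pa), i2h_score(swapped))
  expect_equal(mirror_tree_score(pa), mirror_tree_score(swapped))

  perm <- sample(pa$n_species)
  shuffled <- structure(list(species_list = pa$species_list[perm],
                             rows_a = pa$rows_a[perm], rows_b = pa$rows_b[perm],
                             n_species = pa$n_species),
                        class = "tcs_paired_alignment")
  expect_equal(i2h_score(shuffled), i2h_score(pa))
  expect_equal(mirror_tree_score(shuffled), mirror_tree_score(pa))
})

test_that("i2h signals missing evidence when one protein has no variable columns", {
  const_rows <- setNames(rep("AAAAA", 5), paste0("sp", 1:5))
  sim <- simulate_coevolving_msas(n_species = 5, msa_length = 5, coupling = 0, seed = 2)
  pa <- structure(list(species_list = names(const_rows),
                       rows_a = sim$msa_a$rows, rows_b = const_rows,
                       n_species = 5),
                  class = "tcs_paired_alignment")
  expect_true(is.na(i2h_score(pa)))
})

test_that("identity distances count mismatching non-gap columns", {
  same <- setNames(rep("MKTA", 4), paste0("sp", 1:4))
  expect_true(all(identity_distance_matrix(same) == 0))

  rows <- c(a = "AAAA", b = "AAAT", c = "TTTT")
  d <- identity_distance_matrix(rows)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 1.0)
  expect_equal(d, t(d))

  set.seed(3)
  alphabet <- c("A", "C", "D", "-")
  rand <- setNames(vapply(1:5, function(i)
    paste(sample(alphabet, 12, replace = TRUE), collapse = ""), character(1)),
    paste0("sp", 1:5))
  dm <- tryCatch(identity_distance_matrix(rand), error = function(e) NULL)
  if (!is.null(dm)) {
    for (k in 1:4) for (l in (k + 1):5) {
      ck <- strsplit(rand[k], "")[[1]]
      cl <- strsplit(rand[l], "")[[1]]
      ok <- ck != "-" & cl != "-"
      expect_equal(dm[k, l], 1 - sum(ck[ok] == cl[ok]) / sum(ok))
    }
  }

  no_overlap <- c(a = "AA--", b = "--CC", c = "AACC")
  expect_error(identity_distance_matrix(no_overlap), class = "tcsmeta_data_error")
})

test_that("mirror-tree scores identical histories at 1 and flags constant matrices", {
  sim <- simulate_coevolving_msas(n_species = 10, msa_length = 30, coupling = 0, seed = 4)
  pa_same <- structure(list(species_list = names(sim$msa_a$rows),
                            rows_a = sim$msa_a$rows, rows_b = sim$msa_a$rows,
                            n_species = 10),
                       class = "tcs_paired_alignment")
  expect_equal(mirror_tree_score(pa_same), 1.0)

  const <- setNames(rep("AAAA", 4), paste0("sp", 1:4))
  pa_const <- structure(list(species_list = names(const),
                             rows_a = const, rows_b = sim$msa_a$rows[1:4],
                             n_species = 4),
                        class = "tcs_paired_alignment")
  s <- mirror_tree_score(pa_const)
  expect_equal(as.numeric(s), 0)
  expect_true(isTRUE(attr(s, "missing_evidence")))
})

test_that("mirror-tree ranks alignments by planted coupling", {
  couplings <- c(0, 0.25, 0.5, 0.75, 1)
  scores <- vapply(couplings, function(cp) {
    sim <- simulate_coevolving_msas(n_species = 24, msa_length = 40,
                                    coupling = cp, seed = 77)
    mirror_tree_score(build_paired_alignment(sim$msa_a, sim$msa_b,
                                             min_species = 3))
  }, numeric(1))
  expect_gt(cor(couplings, scores, method = "spearman"), 0)
  expect_gt(scores[5], scores[1])
})
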