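#' Multiple sequence alignment keyed by species
#'
#' A `tcs_msa` is a light container for one protein's alignment: a named
#' character vector of equal-length aligned sequences (gap character `-`),
#' names being species tags, plus the identifier of the query protein the
#' alignment was built for.
#'
#' @param rows named character vector of aligned sequences; names are species
#'   tags, unique.
#' @param query_id identifier of the query protein.
#' @return An object of class `tcs_msa` with fields `query_id`, `rows`
#'   (named character vector) and `length` (alignment columns).
#' @examples
#' msa <- tcs_msa(c(sp1 = "MK-A", sp2 = "MKQA"), query_id = "hk1")
#' msa$length
#' @export
tcs_msa <- function(rows, query_id = NA_character_) {
  if (length(rows) < 1L) abort("an alignment needs at least one sequence", class = "tcsmeta_format_error")
  if (is.null(names(rows)) || anyNA(names(rows)) || any(names(rows) == "")) {
    abort("every alignment row must carry a species tag", class = "tcsmeta_format_error")
  }
  if (anyDuplicated(names(rows))) {
    abort("duplicate species tags in alignment", class = "tcsmeta_format_error")
  }
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    abort("ragged alignment: rows have unequal lengths", class = "tcsmeta_format_error")
  }
  if (widths[1] == 0L) {
    abort("alignment of length 0", class = "tcsmeta_format_error")
  }
  structure(
    list(query_id = query_id, rows = rows, length = unname(widths[1])),
    class = "tcs_msa"
  )
}

#' @export
print.tcs_msa <- function(x, ...) {
  cat(sprintf(
    "<tcs_msa> query %s: %d species x %d columns\n",
    x$query_id %||% "?", length(x$rows), x$length
  ))
  invisible(x)
}

# Species tag from a FASTA header. Convention: a trailing bracketed organism
# name "[Genus species]" if present, otherwise the first whitespace-delimited
# token. Overridable via a regex whose first capture group is the tag.
parse_species_tag <- function(header, species_regex = NULL) {
  if (!is.null(species_regex)) {
    m <- regmatches(header, regexec(species_regex, header))[[1]]
    if (length(m) >= 2) return(m[2])
    return(NA_character_)
  }
  m <- regmatches(header, regexec("\\[([^][]+)\\]\\s*$", header))[[1]]
  if (length(m) >= 2) return(m[2])
  strsplit(trimws(header), "\\s+")[[1]][1]
}

#' Read an aligned FASTA file as a species-keyed alignment
#'
#' Species are parsed from record headers: a trailing bracketed organism name
#' (`>id some text [Genus species]`) when present, else the first token of the
#' header. If two records resolve to the same species, the row with the
#' highest ungapped identity to the first record (taken as the query) is kept
#' and a warning is raised.
#'
#' @param path path to an aligned FASTA file.
#' @param query_id identifier for the query protein; defaults to the first
#'   header token of the first record.
#' @param species_regex optional regex overriding the header convention; its
#'   first capture group is used as the species tag.
#' @return A [tcs_msa()] object.
#' @export
read_msa <- function(path, query_id = NULL, species_regex = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "tcsmeta_data_error")
  aln <- Biostrings::readBStringSet(path)
  if (length(aln) == 0L) abort("empty FASTA file", class = "tcsmeta_format_error")
  seqs <- toupper(as.character(aln))
  headers <- names(aln)
  species <- vapply(headers, parse_species_tag, character(1), species_regex = species_regex)
  if (anyNA(species)) abort("species tag not parseable from FASTA header", class = "tcsmeta_format_error")
  if (is.null(query_id)) query_id <- strsplit(trimws(headers[1]), "\\s+")[[1]][1]
  if (anyDuplicated(species)) {
    ref <- seqs[1]
    keep <- vapply(split(seq_along(seqs), species), function(idx) {
      if (length(idx) == 1L) return(idx)
      ids <- vapply(seqs[idx], function(s) aligned_identity(ref, s), numeric(1))
      idx[which.max(ids)]
    }, integer(1))
    warn("duplicate species in alignment; keeping highest-identity row per species")
    keep <- sort(unname(keep))
    seqs <- seqs[keep]
    species <- species[keep]
  }
  tcs_msa(setNames(unname(seqs), unname(species)), query_id = query_id)
}

#' Write a species-keyed alignment as aligned FASTA
#'
#' Headers are `>species_tag`; [read_msa()] on the output reproduces the
#' alignment exactly (lossless round trip).
#'
#' @param msa a [tcs_msa()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  stopifnot(inherits(msa, "tcs_msa"))
  lines <- as.vector(rbind(paste0(">", names(msa$rows)), unname(msa$rows)))
  writeLines(lines, path)
  invisible(path)
}

# Fraction of columns identical between two already-aligned equal-length
# sequences, over columns where neither is a gap. Returns 0 when nothing is
# comparable.
aligned_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ok <- ca != "-" & cb != "-"
  if (!any(ok)) return(0)
  mean(ca[ok] == cb[ok])
}

#' Filter homolog hits by identity window and coverage
#'
#' Retains hits whose percent identity lies inside `[min_id, max_id]` and
#' whose alignment coverage is at least `min_cov` — the standard pruning of
#' nearly identical and highly diverged homologs applied before building the
#' alignments the coevolution scores depend on.
#'
#' @param hits a data frame with numeric columns `pct_identity` and
#'   `coverage`, both in percent (0-100).
#' @param min_id,max_id identity window bounds in percent. Defaults 30 and 95.
#' @param min_cov minimum coverage in percent. Default 70.
#' @return The retained rows of `hits`, as a tibble.
#' @examples
#' hits <- tibble::tibble(seq = c("a", "b", "c"),
#'                        pct_identity = c(99, 50, 20), coverage = 90)
#' filter_homologs(hits)
#' @export
filter_homologs <- function(hits, min_id = 30, max_id = 95, min_cov = 70) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) return(as_tibble(hits))
  if (!all(c("pct_identity", "coverage") %in% names(hits))) {
    abort("hits needs columns pct_identity and coverage", class = "tcsmeta_data_error")
  }
  rng <- range(c(hits$pct_identity, hits$coverage))
  if (rng[1] < 0 || rng[2] > 100) {
    abort("identities and coverages must lie in [0, 100]", class = "tcsmeta_data_error")
  }
  hits %>%
    filter(.data$pct_identity >= min_id, .data$pct_identity <= max_id,
           .data$coverage >= min_cov) %>%
    as_tibble()
}

#' Pair two alignments on their common species
#'
#' Restricts both alignments to species present in each, the matched-row
#' input required by the correlated-mutation and mirror-tree scores. If more
#' than `max_species` species are shared, the `max_species` species whose
#' rows are most similar to the respective query sequences are kept (ranked
#' by the mean of the two per-protein identities to the query row, ties
#' broken lexicographically by species tag). Fewer than `min_species` shared
#' species is an error: the coevolution features for such a pair are
#' considered missing.
#'
#' @param msa_a,msa_b [tcs_msa()] objects for the two proteins.
#' @param min_species,max_species bounds on the number of shared species
#'   (defaults 25 and 50).
#' @return An object of class `tcs_paired_alignment`: list with
#'   `species_list`, `rows_a`, `rows_b` (named character vectors in matching
#'   species order) and `n_species`.
#' @export
build_paired_alignment <- function(msa_a, msa_b, min_species = 25, max_species = 50) {
  stopifnot(inherits(msa_a, "tcs_msa"), inherits(msa_b, "tcs_msa"))
  common <- intersect(names(msa_a$rows), names(msa_b$rows))
  if (length(common) < min_species) {
    abort(
      sprintf("only %d species shared; %d required", length(common), min_species),
      class = "tcsmeta_insufficient_overlap"
    )
  }
  if (length(common) > max_species) {
    qa <- msa_a$rows[[1]]
    qb <- msa_b$rows[[1]]
    mean_id <- vapply(common, function(sp) {
      (aligned_identity(qa, msa_a$rows[[sp]]) + aligned_identity(qb, msa_b$rows[[sp]])) / 2
    }, numeric(1))
    ord <- order(-mean_id, common)
    common <- common[ord][seq_len(max_species)]
  }
  common <- sort(common)
  structure(
    list(
      species_list = common,
      rows_a = msa_a$rows[common],
      rows_b = msa_b$rows[common],
      n_species = length(common)
    ),
    class = "tcs_paired_alignment"
  )
}

#' @export
print.tcs_paired_alignment <- function(x, ...) {
  cat(sprintf(
    "<tcs_paired_alignment> %d common species; columns %d x %d\n",
    x$n_species, nchar(x$rows_a[1]), nchar(x$rows_b[1])
  ))
  invisible(x)
}
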