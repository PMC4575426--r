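#' A single annotated reference genome
#'
#' Bundles what the genome-context features need from one genome: gene
#' coordinates (1-based inclusive, GFF3 convention), the proteome as a named
#' character vector of amino-acid sequences, operon/transcription-unit
#' assignments (carried on the gene table), and the genome's 16S rRNA
#' sequence used for evolutionary-distance weighting.
#'
#' @param genome_id genome identifier.
#' @param genes data frame with columns `gene_id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `operon_id` (character, `NA` when unassigned).
#' @param proteome named character vector, `gene_id` to amino-acid sequence.
#' @param rrna_16s 16S rRNA nucleotide sequence (may be `NA`).
#' @return An object of class `tcs_genome`.
#' @export
genome_annotation <- function(genome_id, genes, proteome = character(), rrna_16s = NA_character_) {
  stopifnot(is.data.frame(genes))
  needed <- c("gene_id", "start", "end", "strand")
  if (!all(needed %in% names(genes))) {
    abort(paste0("gene table needs columns ", paste(needed, collapse = ", ")),
          class = "tcsmeta_data_error")
  }
  genes <- as_tibble(genes)
  if (!"operon_id" %in% names(genes)) genes$operon_id <- NA_character_
  genes$operon_id <- as.character(genes$operon_id)
  if (anyDuplicated(genes$gene_id)) {
    abort("duplicate gene_id within genome", class = "tcsmeta_data_error")
  }
  if (any(genes$start >= genes$end)) {
    abort("gene coordinates must satisfy start < end (1-based inclusive)",
          class = "tcsmeta_data_error")
  }
  structure(
    list(genome_id = genome_id, genes = genes,
         proteome = proteome, rrna_16s = rrna_16s),
    class = "tcs_genome"
  )
}

#' @export
print.tcs_genome <- function(x, ...) {
  cat(sprintf("<tcs_genome> %s: %d genes, %d proteins, 16S %s\n",
              x$genome_id, nrow(x$genes), length(x$proteome),
              if (is.na(x$rrna_16s)) "absent" else "present"))
  invisible(x)
}

#' A set of reference genomes with aggregation weights
#'
#' The genome-context features (fusion, neighbourhood, operon, profile) are
#' evaluated per reference genome and aggregated with weights that decay with
#' evolutionary distance from the target organism: `w = 1 / (1 + d)`, with
#' `d` the 16S-derived distance. Bounded, positive, and decreasing in
#' distance, so close relatives count more without distant genomes vanishing.
#'
#' @param genomes list of [genome_annotation()] objects.
#' @param distances named numeric vector of evolutionary distances (>= 0) to
#'   the target organism, one per genome; defaults to 0 (equal weights). When
#'   a target 16S sequence is given, distances are computed from each
#'   genome's 16S via [evolutionary_distance_16s()].
#' @param target_16s optional 16S rRNA sequence of the target organism.
#' @return An object of class `tcs_genome_set` with fields `genomes`,
#'   `distances`, `weights`.
#' @export
reference_genome_set <- function(genomes, distances = NULL, target_16s = NULL) {
  stopifnot(is.list(genomes), length(genomes) >= 1)
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids)) abort("duplicate genome_id", class = "tcsmeta_data_error")
  names(genomes) <- ids
  if (is.null(distances)) {
    if (!is.null(target_16s)) {
      distances <- vapply(genomes, function(g) {
        if (is.na(g$rrna_16s)) 0 else evolutionary_distance_16s(target_16s, g$rrna_16s)
      }, numeric(1))
    } else {
      distances <- setNames(rep(0, length(genomes)), ids)
    }
  }
  distances <- distances[ids]
  if (anyNA(distances) || any(distances < 0)) {
    abort("a non-negative distance is required for every genome", class = "tcsmeta_data_error")
  }
  weights <- 1 / (1 + distances)
  structure(list(genomes = genomes, distances = distances, weights = weights),
            class = "tcs_genome_set")
}

#' @export
print.tcs_genome_set <- function(x, ...) {
  cat(sprintf("<tcs_genome_set> %d genomes; weight range [%.3f, %.3f]\n",
              length(x$genomes), min(x$weights), max(x$weights)))
  invisible(x)
}

#' Read a genome bundle directory described by a JSON manifest
#'
#' The manifest (`manifest.json`) lists one entry per genome with fields
#' `genome_id`, `genes` (5-column TSV: gene_id, start, end, strand,
#' operon_id), `proteome` (FASTA) and optionally `rrna_16s` (FASTA), all
#' relative to the bundle directory.
#'
#' @param dir bundle directory containing `manifest.json`.
#' @param target_16s optional target-organism 16S sequence for distance
#'   weighting.
#' @return A [reference_genome_set()].
#' @export
read_genome_bundle <- function(dir, target_16s = NULL) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(paste0("no manifest.json under ", dir), class = "tcsmeta_data_error")
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  genomes <- lapply(seq_len(nrow(manifest)), function(i) {
    entry <- manifest[i, ]
    genes <- readr::read_tsv(file.path(dir, entry$genes), show_col_types = FALSE,
                             progress = FALSE,
                             col_types = readr::cols(
                               gene_id = "c", start = "d", end = "d",
                               strand = "c", operon_id = "c"))
    prot <- Biostrings::readAAStringSet(file.path(dir, entry$proteome))
    proteome <- setNames(as.character(prot), sub("\\s.*$", "", names(prot)))
    rrna <- NA_character_
    if (!is.null(entry$rrna_16s) && !is.na(entry$rrna_16s)) {
      r <- Biostrings::readBStringSet(file.path(dir, entry$rrna_16s))
      if (length(r) > 0) rrna <- as.character(r[[1]])
    }
    genome_annotation(entry$genome_id, genes, proteome, rrna)
  })
  reference_genome_set(genomes, target_16s = target_16s)
}

#' Write a reference genome set as a bundle directory
#'
#' Inverse of [read_genome_bundle()]: emits `manifest.json`, a gene TSV, a
#' proteome FASTA and (when present) a 16S FASTA per genome. All files are
#' plain text.
#'
#' @param gs a [reference_genome_set()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_bundle <- function(gs, dir) {
  stopifnot(inherits(gs, "tcs_genome_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(gs$genomes, function(g) {
    stem <- g$genome_id
    readr::write_tsv(g$genes, file.path(dir, paste0(stem, ".genes.tsv")), progress = FALSE)
    writeLines(as.vector(rbind(paste0(">", names(g$proteome)), unname(g$proteome))),
               file.path(dir, paste0(stem, ".faa")))
    rrna_file <- NA_character_
    if (!is.na(g$rrna_16s)) {
      rrna_file <- paste0(stem, ".16s.fna")
      writeLines(c(paste0(">", stem, "_16S"), g$rrna_16s), file.path(dir, rrna_file))
    }
    list(genome_id = stem, genes = paste0(stem, ".genes.tsv"),
         proteome = paste0(stem, ".faa"), rrna_16s = rrna_file)
  })
  manifest <- dplyr::bind_rows(lapply(entries, as_tibble))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, na = "null", pretty = TRUE)
  invisible(dir)
}

#' Read gene coordinates from a GFF3 file
#'
#' Extracts `gene` (or, when absent, `CDS`) records into the 5-column gene
#' table used by [genome_annotation()]. The gene identifier is the `ID`
#' attribute (or `locus_tag` when `ID` is missing); an `operon_id` attribute
#' is honoured when present, otherwise operon assignments stay `NA` and can
#' be supplied separately.
#'
#' @param path path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `start`, `end`, `strand`,
#'   `operon_id`.
#' @export
read_genes_gff3 <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "tcsmeta_data_error")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  fields <- fields[lengths(fields) == 9L]
  if (length(fields) == 0L) abort("no GFF3 feature lines found", class = "tcsmeta_format_error")
  m <- do.call(rbind, fields)
  types <- m[, 3]
  keep <- types == "gene"
  if (!any(keep)) keep <- types == "CDS"
  m <- m[keep, , drop = FALSE]
  attr_get <- function(attrs, key) {
    val <- stringr::str_match(attrs, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
    val
  }
  ids <- attr_get(m[, 9], "ID")
  lt <- attr_get(m[, 9], "locus_tag")
  ids[is.na(ids)] <- lt[is.na(ids)]
  tibble(
    gene_id = ids,
    start = as.numeric(m[, 4]),
    end = as.numeric(m[, 5]),
    strand = m[, 7],
    operon_id = attr_get(m[, 9], "operon_id")
  )
}
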