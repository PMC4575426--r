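---
title: "Scoring two-component system pairings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring two-component system pairings: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcsmeta)
```

## The problem

Prokaryotic two-component systems (TCS) transduce signals through a
histidine kinase (HK) that phosphorylates a cognate response regulator
(RR). Pairing is highly specific, most genomes encode many HKs and RRs,
and the genes are often not adjacent ("orphan" pairs), so predicting which
HK phosphorylates which RR from sequence alone is a real inference
problem. `tcsmeta` scores a candidate HK–RR pair by computing six
independent interaction signals and fusing them with a class-weighted
RBF-kernel support vector machine; the whole benchmarking stack (stratified
k-fold cross validation, confusion metrics, ROC/AUC, paired DeLong
comparison) and seeded synthetic-data generators are part of the package,
so every stage is testable offline.

## The six features

All six scores are assembled — in this fixed order — into the
six-dimensional vector the classifier consumes.

**1. Correlated mutations (in-silico two-hybrid, `i2h_score()`).**
Interacting proteins accumulate compensatory mutations. For each alignment
column we build the vector of residue similarities over all unordered
sequence pairs (gapped entries are missing); two columns co-evolve when
these vectors correlate across sequence pairs. The score is the fraction of
inter-protein column pairs (variable columns only) whose Pearson
correlation reaches a cutoff, 0.8 by default. The original method family
offers several index variants; the fraction-above-cutoff is used here
because the downstream classifier only needs a monotone interaction signal.
A *variable* column has at least two distinct non-gap residues and at most
50 % gaps — constant or gappy columns carry no covariation information.
Correlations over fewer than 10 shared entries, or where either vector has
zero variance, are defined as 0 (not `NA`) so feature vectors stay numeric.

The default residue similarity table is BLOSUM62, taken from Biostrings at
run time. Any symmetric table can be substituted via
`read_similarity_table()` (a labelled TSV); the score only requires a
symmetric similarity over the 20 standard residues, and using the
field-standard BLOSUM series avoids hand-maintaining a matrix in the
package.

**2. Mirror-tree (`mirror_tree_score()`).** Interacting proteins tend to
have similar phylogenetic histories. Rather than inferring trees, the score
correlates the two proteins' inter-species distance matrices (the classic
matrix-based formulation of the mirror-tree idea): distance is one minus
fractional identity over mutually ungapped columns — cheap, deterministic
and scale-free under the Pearson correlation that compares the two upper
triangles. No molecular-clock correction is applied (deliberately out of
scope).

Both coevolution scores operate on a *paired alignment*
(`build_paired_alignment()`): the two per-protein alignments restricted to
their common species, bounded between 25 and 50 species by default. Below
the minimum the evidence is considered missing; above the maximum the
species most similar to the two query sequences are kept (ranked by the
mean of the two identities, ties broken lexicographically so the choice is
deterministic). These bounds control alignment diversity, to which both
scores are sensitive. Upstream of alignment building,
`filter_homologs()` prunes hits outside a 30–95 % identity window or under
70 % coverage; the window endpoints are configurable and the defaults are
conventional values for building diverse-but-homologous alignment sets.

**3–6. Genome context (`gf_score()`, `pp_score()`, `gn_score()`,
`go_score()`).** These compare the pair against a reference genome set:

* *Gene fusion*: some genome encodes the two proteins as one hybrid
  coding unit. Evidence in a genome requires a single protein with
  significant local alignments to **both** queries whose aligned spans
  overlap by less than 20 % of the shorter span — the overlap rule
  distinguishes a genuine two-domain fusion from one shared domain that
  happens to match both queries.
* *Phylogenetic profiling*: functionally coupled genes are gained and lost
  together. Presence/absence across genomes is called at an e-value
  cutoff of 1e-5; profile agreement is mutual information in bits, clamped
  to [0, 1], with values below 0.35 bits zeroed. The graded value (not a
  binary flag) is passed to the classifier. A constant profile (present
  everywhere or nowhere) is uninformative and yields a missing feature.
* *Gene neighbourhood*: orthologs of the two proteins separated by at most
  200 bp of intergenic sequence. The gap counts bases strictly between the
  genes; overlapping genes have gap 0. Strand is ignored at this level —
  strand logic belongs to the operon calls, which are produced upstream.
* *Gene operon*: orthologs sharing a transcription-unit assignment. Operon
  calls are consumed as input (the 5-column gene TSV or GFF3 `operon_id`
  attribute); the package does not predict operons.

Per-genome evidence is aggregated as a weighted evidence fraction with
weights `w = 1/(1 + d)`, `d` the 16S rRNA distance between the reference
genome and the target organism (global alignment, Jukes–Cantor correction
`d = -(3/4) ln(1 - 4p/3)`, saturating at 5 when `p >= 0.75` where the
correction is undefined). The weight form is bounded, positive and
decreasing in distance: close relatives count more without distant genomes
vanishing entirely. Genomes where an ortholog cannot be resolved are
*not-evaluable* and excluded from both numerator and denominator, making
the aggregate monotone in added evidence.

Homology is searched with Smith–Waterman local alignment (Biostrings
backend, BLOSUM62, affine gaps 11/1) and mapped onto the e-value scale with
a Karlin–Altschul model `E = K·m·n·exp(-λS)` (λ = 0.267, K = 0.041, the
standard gapped BLOSUM62 constants). This keeps the 1e-5 cutoff semantics
of a BLASTP search while the whole scan stays deterministic and
self-contained; tabular output of an external search tool can be swapped in
at the same interface because only (score, e-value) pairs cross it.

## The meta-classifier

`assemble_features()` produces the six-dimensional vector; missing evidence
is imputed as 0 with a mask bit. The mask is *not* fed to the SVM — the
classifier sees exactly six dimensions — because "no evidence" and "zero
evidence" are operationally identical for every feature (all are
non-negative evidence strengths). A pair with all six features missing is
unpredictable and reported as such rather than silently scored.

`grid_search_train()` selects the error cost `c` and RBF width `g` by
maximizing mean k-fold cross-validated AUC over a powers-of-two lattice
(`c` in 2^-5..2^15, `g` in 2^-15..2^3 by default — the conventional LIBSVM
search lattice), ties resolved toward smaller `c` then smaller `g` so
selection is deterministic. AUC is used as the selection criterion because
it is threshold-free. The minority class is weighted by
`N_majority/N_minority` (LIBSVM per-class weighting), countering the
roughly 1:10 interacting:non-interacting imbalance of curated TCS data.
Rows are canonicalized (sorted by label then feature values) before fold
assignment, so training is invariant to the order examples arrive in.

Decision values are min-max normalized to [0, 1] with bounds **frozen at
training time**; prediction-time values are clamped. Frozen bounds make
scores comparable across prediction batches and keep the pipeline
deterministic (per-batch normalization would let the composition of a batch
change individual scores). The classification threshold for confusion
metrics defaults to 0.5 on the normalized score.

## Evaluation stack

* Sensitivity, specificity, accuracy and MCC from the confusion counts;
  any zero denominator yields 0 with a `degenerate` flag rather than `NaN`,
  keeping result tables numeric (the common convention for MCC).
* AUC is computed exactly as the pairwise-comparison probability with ties
  counted half (Mann–Whitney form); the ROC curve sweeps sorted unique
  scores, so trapezoidal integration of the curve reproduces the same
  number.
* `kfold_split()` stratifies by label; fold sizes within each class differ
  by at most one. `cross_validate()` reports both the pooled-score AUC over
  all held-out examples (the headline number) and the fold-mean AUC,
  since either convention appears in the literature; nested model selection
  uses a smaller inner CV (default 5-fold) to keep cost quadratic rather
  than cubic.
* `compare_roc()` is a paired DeLong test on correlated AUCs — the standard
  choice for comparing two classifiers scored on the same examples. A
  degenerate variance estimate returns p = 1 with a warning instead of
  dividing by zero.

## The synthetic generators

The generators produce data with exactly the statistical structure each
predictor assumes — and nothing more:

* `simulate_coevolving_msas()` evolves each column as a categorical process
  over a latent state per species; a planted fraction of column pairs
  (`coupling`) shares one substitution process across the two proteins, so
  they mutate in lock-step. Defaults (30 species, 150 columns, 5 % residue
  noise, 4 latent states) keep alignments inside the 25–50 common-species
  window and give coupled columns near-unit correlation. The process has
  **no phylogenetic tree**: species are exchangeable, so passing tests show
  signal detection under idealized independence, not robustness to shared
  ancestry, alignment error, or paralog contamination — the main
  confounders in real alignments.
* `simulate_reference_genomes()` (default 8 genomes, 6 background proteins
  each) plants fusion, neighbour, operon and presence events exactly as
  requested and returns the truth table; background gene spacing (400–900
  bp) sits safely above the 200-bp neighbourhood cutoff so no spurious
  evidence arises, and per-genome 16S sequences diverge 1–10 % from a
  common ancestor so aggregation weights are non-trivial.
* `simulate_feature_table()` draws Gaussian features with a per-feature
  shift for the interacting class; defaults (113:1134 class sizes, i2h
  strongest, mirror-tree half, context features a quarter) mirror the
  imbalance and relative method usefulness seen in curated TCS benchmarks.

Fixture sizes used by the test-suite (26–30 species, 30–60 columns, 4–8
genomes, feature tables of 60–300 rows) were chosen once as the smallest
instances where every planted effect is statistically unambiguous.

`synthetic_gold_standard()` reproduces the *structure* of the curated
benchmark — 113 interacting / 1134 non-interacting pairs, 56 neighbouring /
57 orphan positives, six species with realistic per-species ratios — with
entirely synthetic identifiers and genomic layouts. It exists so dataset
splitting, orthogonalization and evaluation can run at the benchmark's true
scale and imbalance; it carries no biological signal. The curated set
itself is consumed as a CSV via `load_pair_dataset()` when available. The
21-pair Caulobacter comparison set ships with the package
(`t_set_scores()`) as published per-pair scores of two predictors, usable
directly for paired ROC comparison.

## Numerical choices and degenerate inputs

* Correlation conventions: zero variance or short overlap gives r = 0;
  constant distance matrices give a mirror-tree score of 0 flagged as
  missing evidence.
* Duplicate species in one alignment keep the row with the highest
  ungapped identity to the query row (with a warning).
* A ragged alignment, a zero-length record, an unknown label token or a
  duplicated pair is a format/parse error naming the offending row —
  errors, not silent repairs.
* All-equal decision values normalize to 0.5 everywhere, and a degenerate
  model predicts 0.5 with a warning.
* Ties in model selection, species pruning and fold assignment are broken
  deterministically (smaller parameters, lexicographic species order,
  seeded shuffles), so every stage is byte-reproducible at a fixed seed.

## Known limitations

* Headline performance numbers on the real curated corpus require
  UniProtKB-scale alignments and a ~243-genome reference panel; at package
  scale all claims are property-level (oracle agreement, planted-event
  recovery, orderings), not reproductions of published AUCs.
* The e-value model uses fixed Karlin–Altschul constants rather than
  sequence-composition-specific ones; adequate for presence calling at
  1e-5, not for reporting calibrated e-values near the cutoff.
* Ortholog resolution is best-hit (optionally reciprocal); no synteny or
  tree-aware orthology.
* No probability calibration of SVM scores and no kernels beyond RBF; no
  bootstrap confidence intervals on AUC (the paired DeLong test covers the
  comparison use case).
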