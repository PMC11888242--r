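---
title: "Calling and comparing gene-cluster windows with proximity-weighted focal scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and comparing gene-cluster windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatorgc)
```

## The problem

Biosynthetic gene clusters (BGCs) and other functional gene neighborhoods
are usually mined with general-purpose rule or model based detectors. When a
scientist instead knows *which* proteins define the pathway of interest,
targeted mining is more direct: declare a set of **required** query proteins
(those essential for the product) and optionally a set of **optional**
queries (tailoring or transport enzymes), and retrieve every genomic region
that carries homologs of all required queries close together on one contig.
`gatorgc` implements that workflow end to end for bacterial genomes in
GenBank format: window calling, all-vs-all window comparison with a
proximity-weighted similarity score, deduplication, conservation and
taxonomic-diversity summaries, and vector figures.

## The model and its assumptions

### Window calling

Every database gene hit by a required query is a candidate anchor. On each
contig, candidate anchors are chained by single linkage using the
intergenic gap `max(0, later.start - earlier.end)`; a chain is a **GATOR
window** when it contains at least one hit for *every* required query.
Three rules therefore govern calling: (i) all required queries on the same
contig, (ii) chaining gaps at most `required_distance`, and (iii) a fixed
`window_extension` flank added on both sides of the called core span.

- `required_distance` defaults to **85,900 bp**, the 95th percentile of
  within-cluster intergenic distances over curated, experimentally
  validated BGCs. `estimate_default_distance()` recomputes this statistic
  for any reference cluster set (all within-cluster gene pairs pooled,
  percentile by linear interpolation, R quantile type 7).
- `window_extension` defaults to **10,000 bp** per side, clamped to contig
  bounds; genes partially overlapping the extended span are included.
- Genes within **500 bp** of a contig end are flagged `contig_edge`,
  signalling possible truncation by an assembly break.

Single-linkage chaining admits long multi-gene clusters whose end-to-end
span exceeds the cutoff; a strict all-pairs mode (`linkage = "complete"`)
is available where that is not wanted. Windows whose extended spans overlap
on one contig are merged by default (`merge_overlapping = FALSE` restores
one window per chain); merging avoids double-counting near-tandem loci in
the all-vs-all comparison.

### Homology evidence

Homology is a pluggable contract. Production-scale searches come from an
external aligner's 12/13-column tabular output (`load_tabular_hits()`),
filtered at **70% query coverage** and **35% identity** by default; query
coverage is aligned query span over query length. At desk scale
`builtin_search()` computes the same contract with Smith–Waterman local
alignment (BLOSUM62, gap open 11 / extend 1, via `Biostrings`); bit scores
use the gapped BLOSUM62 Karlin–Altschul constants. Modular megasynthases
(NRPS/PKS) evolve by domain shuffling, so sequence-level thresholds are a
poor retrieval criterion for them: queries and database proteins carrying
at least one adenylation (A) and one condensation (C) domain are NRPS, at
least one acyltransferase (AT) plus one ketosynthase (KS) are PKS, both
rules together give a hybrid; modular queries match database proteins by
category membership instead of similarity (inclusively: NRPS matches NRPS
and hybrids; `hybrid_mode = "strict"` requires equality). Domain evidence
is ingested from HMMER-style domain tables at an e-value of **1e-4**, with
the profile-name-to-domain map shipped as an editable table
(`default_profile_map()`).

### The GATOR Focal Score

To compare windows, one window serves as the focal window and each of its
genes is tested for presence (at least one passing homology hit) in every
other window. Genes are weighted by proximity to the query-anchored genes
with a decaying Gaussian kernel: an anchor gene has weight exactly 1, a
gene at distance `d` from an anchor has weight `exp(-d^2 / (2 sigma^2))`,
and a gene near several anchors takes the maximum. The focal score is

$$\mathrm{GFS} = \frac{\sum_g w_g\,[\text{present}_g]}{\sum_g w_g} \in [0, 1],$$

so content near the functional core dominates and distant flank genes
contribute little. Distance is measured in **gene ordinal index** by
default, which makes the score invariant to intergenic-length noise; a
bp-based kernel is available (`mode = "bp"`). The bandwidth defaults to
`sigma = max(1, n_genes / 6)`, which lets an anchor at one window edge
decay to essentially zero at the far edge of the window; it is fully
configurable, and all reported comparisons here use the default.

Identical windows are removed before plotting: focal windows are processed
in descending genomic length (ties by window id), anything scoring
`GFS >= 1 - 1e-9` against the current focal is recorded as its duplicate
and dropped, and a window that has served as focal is a final
representative. The tolerance absorbs floating-point summation order; the
identity criterion itself is exact. Because the test is one-directional, a
shorter window whose genes are all present in a longer focal is removed by
it; `mutual = TRUE` requires identity in both directions, keeping strict
subset windows separate.

### Conservation and diversity

Per-gene conservation of a focal window is the fraction of windows (focal
row included) in which the gene is present, computed from the
presence–absence tables; figures render it as fill opacity. By default
conservation and the score matrix are computed over the deduplicated set
(`conservation_basis = "all"` switches to every called window). Taxonomic
diversity of a window family is Shannon entropy in bits,
`H = -sum p_i log2 p_i`, over window counts per taxon at a chosen rank;
entropies are labelled by the interquartile rule: up to Q3 **low** (values
below Q1 are by construction low diversity), within the right whisker
(Q3, Q3 + 1.5 IQR] **medium**, beyond it **high**. Quartiles use linear
interpolation. The all-vs-all matrix is ordered for the heatmap by
complete-linkage hierarchical clustering of Euclidean row distances.

## What the synthetic generator emulates

`plant_spec()`/`generate_synthetic()` build multi-contig genomes around one
cluster template (required, optional and filler genes with fixed gaps drawn
once from 200–2,000 bp, protein lengths 60–110 aa, uniform-random residues,
reverse-translated with the bacterial code). Copy instructions plant exact
duplicates, gene dropouts, protein replacements, controlled point-mutated
variants (`mutate_protein()` hits a target identity within two points),
contig-edge truncations and decoys missing a required gene; unrelated noise
genes live on a second contig, and loci on one contig are separated by more
than the chaining cutoff. The generator emits ground truth (expected
windows, duplicate groups, per-gene conservation) that the tests compare
against pipeline output.

The generator deliberately does **not** model codon usage, GC content,
pseudogenes, overlapping genes, or the continuous gradient of homology
found in real pan-genomes: planted homologs are either (near-)identical or
unrelated. Passing tests therefore demonstrate the correctness of the
calling, scoring and deduplication *logic* under controlled conditions,
not retrieval sensitivity on diverged natural sequences — that depends on
the external aligner's sensitivity and the user's thresholds.

## Numerical and design choices

- Coordinates are 0-based half-open internally; all GenBank and header I/O
  converts to 1-based inclusive. Compound (`join`) locations take the
  minimal enclosing span for coordinates but translate the joined exons.
- Translation fallback uses genetic code table 11, trims one trailing stop
  and rejects internal stops (the CDS is skipped with a warning). A
  `/translation` qualifier, when present, is stored verbatim.
- Protein-db headers are pipe-delimited
  (`genome|contig|start|end|strand|locus|product`); pipes inside free text
  become `_` so headers always round-trip.
- A gene claimed by several queries resolves by precedence required >
  optional, then highest bit score, then lexicographic query id.
- Degenerate inputs: an empty window set is a valid result, not an error;
  a window without query-assigned genes cannot be weighted and errors; a
  1-row score matrix clusters trivially with no tree; fewer than four
  entropy values cannot support an IQR split and are all labelled low.
- Figures are plain SVG with one element per glyph and machine-readable
  `data-*` attributes, so colors, opacities and glyph counts are testable;
  colors follow the field convention (required purple `#800080`, optional
  orange `#FFA500`, other green `#008000`, contig-edge outline red).

## Problem sizes used in the shipped checks

The test-suite and acceptance fixtures use 7–10 genomes with 6–7-gene
templates, 50 random genomes of 30–200 genes for the brute-force
window-calling comparison, 1,000 random windows for the score-algebra
properties and 100 random pools for the percentile oracle. These sizes
exercise every code path while keeping the default run fast; all of them
scale up linearly if larger checks are wanted.

## Limitations

- The built-in search is exact Smith–Waterman and intended for desk-scale
  inputs (up to a few thousand proteins); genuine database mining should
  feed external aligner output through the tabular contract.
- Modular-domain assignment requires externally computed domain tables;
  the package ships the profile-name map, not the HMMs.
- Window boundaries are rule-based only; no probabilistic refinement.
- Taxonomy is user-supplied labels; no classification is performed.

## A worked run

```{r run, eval = FALSE}
spec <- plant_spec(n_genomes = 7, seed = 11, loci = c(
  rep(list(list(list(type = "exact"))), 5),
  list(list(list(type = "dropout", drop = "opt1"))),
  list(list(list(type = "decoy")))))
syn <- generate_synthetic(spec, out_dir = "fixture")

cfg <- gator_config(
  genomes = list.files("fixture", pattern = "gbk$", full.names = TRUE),
  required = "fixture/queries_required.faa",
  optional = "fixture/queries_optional.faa",
  out_dir = "gator_out")
res <- gator_mine(cfg)

length(res$windows)          # 6 called windows (the decoy is skipped)
length(res$unique_windows)   # 2 after deduplication
res$gfs                      # all-vs-all focal scores of the unique set
```
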