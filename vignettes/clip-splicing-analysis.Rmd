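---
title: "CLIP cluster calling, YCAY motif enrichment and cassette-exon splicing integration"
author: "clipmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CLIP cluster calling, YCAY motif enrichment and cassette-exon splicing integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipmap)
```

## What the package models

HITS-CLIP maps the positions where an RNA-binding protein contacts RNA
in vivo: crosslinked protein-RNA fragments are sequenced and aligned,
and each uniquely mapped, duplicate-collapsed read (a *CLIP tag*) marks
a candidate contact as a short stranded genomic interval. For a
splicing regulator such as NOVA1/NOVA2, the analytical questions are
(i) where does the protein bind (clusters of tags, and their sequence
signature — for NOVA the YCAY element, Y ∈ {C, U}); (ii) which
cassette exons change inclusion when the protein is removed (ΔI between
wild-type and knockout); and (iii) which changed exons are *direct*
targets, i.e. carry motif-bearing binding clusters on the alternative
exon or its flanking introns. `clipmap` implements this chain
end-to-end at desk scale, together with a synthetic-data generator that
plants binding sites and inclusion changes so every stage can be
validated against known truth.

## Coordinate and strand conventions

Internally every interval is a `GRanges`: 1-based, closed, the native
R/Bioconductor convention. BED input and output (0-based half-open) is
converted on read and write; GTF (1-based closed) is used as-is. This
was a deliberate choice over carrying a BED-style convention inside the
package: all interval arithmetic is delegated to `IRanges`, and a
single native convention removes a whole class of off-by-one errors.
Every interval must carry an explicit `+`/`-` strand and
opposite-strand features never interact: CLIP is strand-resolved, so
tags, clusters, annotation and motif lookups are all strand-matched,
and antisense overlap counts as no overlap.

## Cluster calling: BC and PH

Tags are first collapsed to unique tags within each replicate, keying
on the full `(chrom, start, end, strand)` tuple — at interval level,
same-coordinate reads are the available PCR-duplicate signature
(barcode-aware deduplication would need read-level data, which is out
of scope). Clusters are then the connected components of unique tags
under ≥ 1 nt same-strand overlap. Abutting tags (zero gap) do *not*
join: strict overlap is the conservative reading of a "pileup".

Each cluster carries:

* `bc` — *biological complexity*: the number of replicates
  contributing at least one tag anywhere in the cluster. `BC2` (≥ 2 of
  3 replicates) is the working set for all downstream analyses.
* `ph` — *peak height*: the maximum per-base tag depth inside the
  cluster. "Peak height" is inherently a positional depth concept, so
  we define PH as maximum depth rather than total tag count; the total
  is exposed separately as `total_tags`, so a count-based filter is one
  argument away (`filter_clusters` accepts any combination).

`filter_clusters()` keeps exactly the clusters with `bc >= min_bc` and
`ph >= min_ph` and reports the pass rate as a whole-number percentage
(half rounded up), matching how such rates are conventionally quoted.

## Motif analysis

The motif layer works on RNA (`A,C,G,U,N`; `N` never matches
anything). `ycay_scan()` reports every window matching `[CU]CA[CU]`,
overlapping matches included. Tetramer counting pools overlapping 4-nt
windows across all cluster sequences (`Biostrings`
`oligonucleotideFrequency`), skipping windows that contain `N`.

The null model for enrichment is a *within-sequence mononucleotide
permutation*: each control sequence preserves its length and exact base
composition. This is the minimal null consistent with "shuffled
control sequences" — it asks whether the *arrangement* of bases into
motifs is surprising given the composition. Dinucleotide-preserving
shuffles would additionally control for local structure bias but also
absorb part of the signal of interest for a 4-mer; they are out of
scope. Defaults: 100 shuffles, seeded, with
`enrichment = (observed + 1) / (shuffled mean + 1)`; the unit
pseudocount keeps ratios finite for absent tetramers. Ties in the
ranking break lexicographically so the table is fully deterministic.

Positional YCAY profiles anchor each cluster at its midpoint
(`(start + end) %/% 2` — deterministic and symmetric), extract
strand-matched RNA over `[-flank, +flank]` (default flank 500 nt,
configurable; windows running off a chromosome end are dropped), and
compare per-offset YCAY start frequencies against the same windows
shuffled. The shuffle SD is reported so that profile deviations can be
judged against the null spread.

## Genomic region assignment

A cluster's region label is decided at its midpoint anchor, against
same-strand transcripts only. Exonic anchors are sub-classified by the
transcript's CDS bounds in transcript orientation (5' UTR / CDS /
3' UTR); anchors inside a transcript span but outside exons are
intronic; everything else is intergenic. Conflicting isoforms resolve
by precedence exonic > intron > intergenic and, within exonic,
CDS > UTR — consistent with reporting the exon subtotals as mutually
exclusive. Two further conventions, chosen for determinism and an
exhaustive label set: exon hits in transcripts lacking CDS annotation
fall in the `cds` bucket, and anchors (not maximal-overlap bases)
decide labels for clusters spanning exon/intron boundaries.

## Splicing quantification

Cassette-exon inclusion is estimated from junction counts pooled across
replicates within each genotype:

* `m = (up_inc + down_inc) / 2` — one included exon is witnessed by
  two junctions, so averaging avoids double-counting;
* `I = m / (m + excl)`, and `ΔI = I_KO − I_WT` (one sign convention,
  used everywhere: positive ΔI means inclusion rises when the protein
  is absent).

Events whose pooled junction total falls below `min_total_reads`
(default 20 per genotype) are excluded before testing — a
low-expression filter; 20 pooled reads is the smallest total at which
an inclusion ratio is estimated to within roughly ±0.1 standard error.
Tested events get a two-sided Fisher exact p-value on
`[[m_wt, excl_wt], [m_ko, excl_ko]]` (m rounded half-up) and
Benjamini-Hochberg FDR across all tested events of the run. The Fisher
test on pooled counts is exact at desk scale; replicate-level
dispersion modelling (edgeR-style) is deliberately out of scope, and
the type-I consequences of pooling are checked empirically by the null
simulations below.

## Target integration and the RNA map

An event is a *target* iff it is significant (|ΔI| ≥ 0.1,
FDR < 0.1 by default) **and** at least one BC2 cluster overlaps
(≥ 1 nt, same strand) its alternative exon or either *full* flanking
intron while containing at least one YCAY match. Using whole flanking
introns (not a fixed window) for support follows the definition of the
regulated-target class; the RNA map, which needs a common axis, uses
fixed flanks instead.

The RNA map summarises tag density around regulated exons on a
composite axis in transcript orientation: `intron_flank` (default
1000 nt) of upstream intron + `exon_flank` (default 50 nt) of exon
around the exon start, then the mirrored segment around the exon end,
binned at 25 nt. Minus-strand events are flipped so profiles always
read 5'→3'. Coverage is normalised *per event* before averaging —
each event's binned coverage sums to 1 — so highly expressed events
cannot dominate the profile; events with no tag coverage are dropped
from the average. Anchoring at the two splice sites (rather than
binning the whole exon) keeps the axis well-defined for exons of
different lengths.

## The synthetic-data generator

`simulation_config()` fixes the study conditions; each generator draws
from its own RNG stream (`seed` plus a fixed offset), so adding or
re-running one generator never perturbs the others and identical seeds
give bit-identical outputs.

* **Genome/annotation** — uniform-random chromosomes; genes tiled
  without overlap on alternating strands, each with ≥ 3 exons
  (150 nt) separated by 1200-nt introns, and a CDS leaving 50-nt UTRs.
  The middle exon is the cassette event.
* **Sites** — `n_sites` genes (the first `n_sites`, so truth is
  deterministic) receive one site of `site_motif_copies` tandem YCAY
  instances written into the genome on the gene's strand: in the
  cassette exon with probability `site_exon_frac`, otherwise in the
  *proximal* downstream intron (100–400 nt from its 5' end), where
  position-dependent splicing regulators such as NOVA concentrate
  inclusion-coupled binding.
* **Tags** — per replicate and site, `Poisson(8)` tags of 30 nt with
  uniform ±10-nt start jitter; background `Poisson(0.5/kb/replicate)`
  uniform over gene spans only (CLIP captures transcribed RNA, and
  keeping background transcribed makes region-assignment tests
  meaningful); every tag is re-emitted at identical coordinates with
  probability `pcr_duplication_rate` (default 0.15) to emulate PCR
  duplicates. Three replicates by default.
* **Junctions** — per event, genotype and replicate, a coverage
  `c ~ Poisson(junction_depth)` (default 100) is drawn and each
  junction sampled independently: `up, down ~ Binom(c, I_true)`,
  `excl ~ Binom(c, 1 − I_true)`. This mimics independent short-read
  sampling at the three junction positions and makes the pooled
  estimator `m/(m + excl)` unbiased for `I_true`; a model that splits
  a single inclusion draw across the two junctions would bias the
  estimator toward `(I/2)/(I/2 + 1 − I)` and break genotype
  comparability at unequal inclusion levels.

What the generator does *not* emulate — and hence what passing tests
cannot show about real data: realistic base composition and mappability
structure, crosslink-induced truncations/mutations, fragment-length and
sequence-specific capture biases, overlapping genes and antisense
transcription, isoform complexity beyond one cassette event per gene,
and biological replicate dispersion beyond Poisson/binomial sampling.
Conclusions about those properties require the real deposited data.

## Validation problem sizes and numerical choices

The shipped test-suite exercises the package at sizes chosen to make
every check statistically decisive while keeping a full run in well
under a coffee break: oracle comparisons on 500–1000-tag simulations
(cluster calling vs an explicit union-find; deduplication vs a key-set
oracle; tetramer counts vs a sliding window; overlap fractions vs an
all-pairs scan), an exhaustive sweep of every 2×2 table with grand
total ≤ 30 against direct hypergeometric enumeration, recovery runs
with 60–100 planted sites over 80–150 genes, ΔI recovery on 200 events
at junction depth 100, and a 2,000-event null (20 seeds × 100 events)
for type-I control. Degenerate inputs are pinned by tests: empty tag
tables, events with all-zero counts (inclusion undefined, event
flagged), events failing the expression filter (no p/FDR), empty
cluster or event sets (errors or warnings as documented), and windows
clipped at chromosome bounds.

## Known limitations

* Interval-level deduplication cannot distinguish genuine same-start
  reads from PCR duplicates; with degenerate barcodes available, the
  collapse would be less aggressive.
* Pooled Fisher testing ignores replicate dispersion; with many
  replicates or overdispersed counts a replicate-aware model should
  replace it.
* Region labels are midpoint-based; clusters straddling an
  exon/intron boundary contribute a single label.
* The motif layer targets a fixed 4-mer class; position-weight-matrix
  or de novo discovery is out of scope.
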