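# clipmap

Strand-aware HITS-CLIP cluster calling, YCAY motif enrichment, and
cassette-exon splicing integration, with a ground-truth synthetic-data
generator.

## The problem

HITS-CLIP maps where an RNA-binding protein touches RNA in vivo: each
uniquely mapped, PCR-duplicate-collapsed read (a *CLIP tag*) is a short
stranded genomic interval marking a candidate contact. For a splicing
regulator such as NOVA1/NOVA2, three analyses have to be combined to
identify directly regulated exons:

1. **Binding** — tags from replicate experiments are collapsed to
   unique tags and clustered by same-strand overlap. Each cluster
   carries its *biological complexity* BC (number of replicates with a
   tag in the cluster; BC2 = supported by ≥ 2 replicates) and its
   *peak height* PH (maximum per-base tag depth). Cluster sequences
   are scored for tetramer enrichment against composition-preserving
   shuffled controls and for the protein's YCAY motif (Y ∈ {C, U}),
   and assigned to genomic regions (5′ UTR / CDS / 3′ UTR / intron /
   intergenic).
2. **Splicing** — cassette-exon inclusion is quantified from junction
   read counts pooled over replicates:
   `I = m / (m + e)` with `m = (u + d)/2`, where `u`, `d` are the
   upstream/downstream inclusion-junction counts and `e` the exclusion
   count; `ΔI = I_KO − I_WT`. Differences are tested with a two-sided
   Fisher exact test on `[[m_WT, e_WT], [m_KO, e_KO]]` and controlled
   by Benjamini–Hochberg FDR, after a low-expression filter.
3. **Integration** — an event is a regulated *target* iff
   `|ΔI| ≥ 0.1`, `FDR < 0.1`, and a YCAY-containing BC2 cluster
   overlaps the alternative exon or a flanking intron. RNA-map
   metagene profiles summarise tag density in 25-nt windows around
   enhanced vs silenced exons.

The package implements all three layers on standard formats (BED6,
GTF, FASTA, TSV) plus a seeded synthetic-data generator that plants
YCAY sites and inclusion shifts so the whole pipeline can be validated
against known truth. It is aimed at computational biologists who want
a small, fully tested, deterministic reference implementation of this
analysis chain.

## Worked example

```r
library(clipmap)

cfg <- simulation_config(
  seed = 20, n_genes = 80, n_sites = 50,
  inclusion_wt = c(rep(0.8, 40), rep(0.5, 40)),
  inclusion_ko = c(rep(0.4, 40), rep(0.5, 40)))
run <- run_pipeline(cfg)
writeLines(pipeline_report(run))
#> clipmap run report
#> seed: 20
#> replicates: 3
#> unique tags per replicate: 431, 454, 431
#> unique tags total: 1316
#> clusters: 350
#> BC>=2 clusters: 55 (16% of all)
#> events tested: 80
#> target events: 40 on 40 genes
```

The 80 genes split into 40 bound + regulated (true ΔI = −0.4, a
planted YCAY site in the cassette exon or proximal downstream intron)
and 40 unbound, unregulated decoys; the pipeline recovers exactly the
40 planted targets. The motif layer ranks tetramers in BC2 cluster
sequences against 20 shuffled controls:

```r
head(run$enrichment[, c("kmer", "observed", "shuffled_mean", "enrichment")], 5)
#>  kmer observed shuffled_mean enrichment
#>  UCAU       49         13.30   3.496503
#>  UUCA       42         11.50   3.440000
#>  CCAU       43         11.95   3.397683
#>  UCAC       41         12.50   3.111111
#>  AUUC       39         12.80   2.898551
```

All top-ranked tetramers are YCAY-conformant or YCAY-overlapping, as
expected when tandem YCAY elements drive the binding signal. Each
target call records its evidence:

```r
head(run$targets[, c("event_id", "delta_i", "fdr", "direction", "support_regions")], 3)
#>  event_id    delta_i          fdr direction   support_regions
#>  g0001_e1 -0.4126790 1.300458e-22  silenced downstream_intron
#>  g0002_e1 -0.3924230 2.217132e-21  silenced downstream_intron
#>  g0003_e1 -0.4323052 2.159104e-26  silenced downstream_intron
```

Negative ΔI means inclusion falls in the knockout, i.e. the protein
enhanced inclusion of these exons; each call is supported by a
YCAY-bearing BC2 cluster in the downstream flanking intron, the classic
position for inclusion-enhancing NOVA binding.

Every stage is also available as a standalone function
(`collapse_duplicates`, `call_clusters`, `filter_clusters`,
`count_tetramers`, `rank_enrichment`, `ycay_positional_profile`,
`assign_region`, `overlap_fraction`, `splicing_table`, `de_filter`,
`define_targets`, `rna_map`, `delta_i_correlation`, ...), reading and
writing the standard interchange formats.

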