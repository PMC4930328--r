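# Small shared simulation configs so module tests stay fast.

small_config <- function(seed = 11L, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chroms = 1L, chrom_length = 80000L,
         n_genes = 18L, n_sites = 12L),
    list(...))
  do.call(simulation_config, args)
}

# A tiny hand-written genome + transcript pair used by annotation and
# integration tests. One coding transcript on '+' with two exons:
# exon1 [101,200], intron [201,400], exon2 [401,500], CDS [151,450].
toy_models <- function(strand = "+") {
  ex <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(101L, 401L),
                                                c(200L, 500L)),
                               strand = strand)
  if (strand == "-") ex <- rev(ex)
  structure(list(transcript_model("t1", "g1", strand, ex,
                                  cds_start = 151L, cds_end = 450L)),
            class = "TranscriptModels")
}

stranded <- function(chrom, start, end, strand = "+", replicate = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  if (!is.null(replicate)) S4Vectors::mcols(gr)$replicate <- replicate
  gr
}
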