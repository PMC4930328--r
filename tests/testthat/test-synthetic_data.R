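test_that("generators are bit-identical under a fixed seed", {
  cfg <- small_config(seed = 7L)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(as.character(a$genome), as.character(b$genome))
  pa <- plant_sites(a$genome, a$transcripts, cfg)
  pb <- plant_sites(b$genome, b$transcripts, cfg)
  expect_identical(as.character(pa$genome), as.character(pb$genome))
  expect_equal(pa$truth$sites, pb$truth$sites)
  ta <- simulate_tags(pa$truth, cfg)
  tb <- simulate_tags(pb$truth, cfg)
  expect_equal(ta, tb)
  ja <- simulate_junctions(pa$truth, cfg)
  jb <- simulate_junctions(pb$truth, cfg)
  expect_identical(ja, jb)
})

test_that("genome construction respects the configured geometry", {
  cfg0 <- simulation_config(n_genes = 0L, n_sites = 0L, n_chroms = 1L,
                            chrom_length = 5000L)
  sim0 <- simulate_genome(cfg0)
  expect_length(sim0$transcripts, 0)
  expect_equal(width(sim0$genome), 5000L)

  cfg2 <- simulation_config(n_genes = 2L, n_sites = 0L, n_chroms = 1L,
                            chrom_length = 20000L, exons_per_gene = 3L)
  sim2 <- simulate_genome(cfg2)
  expect_length(sim2$transcripts, 2)
  for (m in sim2$transcripts)
    expect_length(transcript_introns(m), 2)

  cfg_big <- simulation_config(n_genes = 100L, n_sites = 0L,
                               n_chroms = 1L, chrom_length = 20000L)
  expect_error(simulate_genome(cfg_big), "fit")
})

test_that("planted sites are YCAY-rich and readable back from the genome", {
  cfg <- small_config(seed = 5L, site_motif_copies = 3L)
  sim <- simulate_genome(cfg)
  pl <- plant_sites(sim$genome, sim$transcripts, cfg)
  sites <- pl$truth$sites
  expect_length(sites, cfg$n_sites)
  expect_equal(width(sites), rep(12L, cfg$n_sites))
  rna <- fetch_rna(pl$genome, sites)
  # the written genome reproduces the generator's motif strings exactly,
  # on both strands
  expect_identical(rna, mcols(sites)$rna)
  expect_true(any(as.character(strand(sites)) == "-"))
  for (s in rna)
    expect_gte(length(ycay_scan(s)), 3)

  cfg0 <- small_config(n_sites = 0L)
  pl0 <- plant_sites(sim$genome, sim$transcripts, cfg0)
  expect_length(pl0$truth$sites, 0)
  expect_false(any(pl0$truth$events$bound))
})

test_that("tag simulation obeys rate and duplication contracts", {
  cfg_off <- small_config(tags_per_site_mean = 0,
                          background_tag_rate = 0)
  sim <- simulate_genome(cfg_off)
  pl <- plant_sites(sim$genome, sim$transcripts, cfg_off)
  expect_length(simulate_tags(pl$truth, cfg_off), 0)

  cfg_dup <- small_config(pcr_duplication_rate = 1)
  pl2 <- plant_sites(sim$genome, sim$transcripts, cfg_dup)
  tags <- simulate_tags(pl2$truth, cfg_dup)
  key <- paste(seqnames(tags), start(tags), end(tags), strand(tags),
               mcols(tags)$replicate)
  # every emitted tag is duplicated once, so coordinate counts are even
  expect_true(all(table(key) %% 2 == 0))
  expect_true(all(width(tags) == cfg_dup$tag_length))
})

test_that("site pileups exceed the transcribed background", {
  cfg <- small_config(seed = 19L)
  sim <- simulate_genome(cfg)
  pl <- plant_sites(sim$genome, sim$transcripts, cfg)
  tags <- simulate_tags(pl$truth, cfg)
  cov <- coverage(tags, width = setNames(rep(cfg$chrom_length,
                                             cfg$n_chroms),
                                         paste0("chr",
                                                seq_len(cfg$n_chroms))))
  site_pos <- unlist(lapply(seq_along(pl$truth$sites), function(i) {
    chr <- as.character(seqnames(pl$truth$sites))[i]
    as.numeric(cov[[chr]][start(pl$truth$sites)[i]:
                            end(pl$truth$sites)[i]])
  }))
  spans <- pl$truth$gene_spans
  bg_mask <- setdiff(GRanges(seqnames(spans), ranges(spans)),
                     GRanges(seqnames(pl$truth$sites),
                             ranges(pl$truth$sites) + 40L))
  bg_pos <- unlist(lapply(seq_along(bg_mask), function(i) {
    chr <- as.character(seqnames(bg_mask))[i]
    as.numeric(cov[[chr]][start(bg_mask)[i]:end(bg_mask)[i]])
  }))
  expect_gt(mean(site_pos), mean(bg_pos))
})

test_that("junction counts reflect the true inclusion ratios", {
  cfg1 <- small_config(inclusion_wt = 1, inclusion_ko = 0)
  sim <- simulate_genome(cfg1)
  pl <- plant_sites(sim$genome, sim$transcripts, cfg1)
  jx <- simulate_junctions(pl$truth, cfg1)
  expect_true(all(jx$excl[jx$genotype == "WT"] == 0))
  expect_true(all(jx$up_inc[jx$genotype == "KO"] == 0 &
                    jx$down_inc[jx$genotype == "KO"] == 0))

  # pooled empirical inclusion at depth 10,000 is within +/- 0.02 of 0.5
  # (binomial standard error ~ 0.005 per event at this depth)
  cfg2 <- small_config(seed = 23L, junction_depth = 10000,
                       inclusion_wt = 0.5, inclusion_ko = 0.5)
  pl2 <- plant_sites(sim$genome, sim$transcripts, cfg2)
  jx2 <- simulate_junctions(pl2$truth, cfg2)
  pooled <- rowsum(jx2[, c("up_inc", "down_inc", "excl")],
                   paste(jx2$event_id, jx2$genotype))
  i_hat <- inclusion_ratio(pooled$up_inc, pooled$down_inc, pooled$excl)
  expect_true(all(abs(i_hat - 0.5) < 0.02))
})

test_that("junction tables round-trip through TSV", {
  cfg <- small_config()
  sim <- simulate_genome(cfg)
  pl <- plant_sites(sim$genome, sim$transcripts, cfg)
  jx <- simulate_junctions(pl$truth, cfg)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_junction_table(jx, f)
  expect_identical(read_junction_table(f), jx)
  expect_error(read_junction_table(
    write_junction_table(jx[, -4], f)), "missing column")
})
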