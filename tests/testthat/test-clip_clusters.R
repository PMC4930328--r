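test_that("PCR-duplicate collapsing is per-replicate, idempotent and matches a set oracle", {
  tags <- c(stranded("chr1", 100, 129, "+", 1L),
            stranded("chr1", 100, 129, "+", 1L),
            stranded("chr1", 100, 129, "+", 2L))
  uniq <- collapse_duplicates(tags)
  expect_length(uniq, 2)  # same coords in different replicates both kept
  expect_equal(sort(mcols(uniq)$replicate), c(1L, 2L))
  expect_equal(collapse_duplicates(uniq), uniq)

  rnd <- random_tags(1000, seed = 17, span = 2000)
  uniq2 <- collapse_duplicates(rnd)
  expect_lte(length(uniq2), length(rnd))
  expect_identical(oracle_dedup_keys(uniq2), oracle_dedup_keys(rnd))
  expect_equal(collapse_duplicates(uniq2), uniq2)
  # output is independent of input order
  expect_equal(collapse_duplicates(rnd[sample(length(rnd))]), uniq2)
})

test_that("cluster calling produces per-replicate counts, BC and PH", {
  tags <- c(stranded("chr1", 100, 129, "+", 1L),
            stranded("chr1", 110, 139, "+", 2L),
            stranded("chr1", 120, 149, "+", 3L))
  cl <- call_clusters(tags, n_replicates = 3L)
  expect_length(cl, 1)
  expect_equal(start(cl), 100L)
  expect_equal(end(cl), 149L)
  expect_equal(mcols(cl)$bc, 3L)
  expect_equal(mcols(cl)$total_tags, 3L)
  expect_equal(mcols(cl)$ph, 3L)  # all three tags cover bases 120..129

  # a 1-nt gap separates clusters; so do abutting tags (strict overlap)
  two <- c(stranded("chr1", 100, 129, "+", 1L),
           stranded("chr1", 131, 160, "+", 1L))
  expect_length(call_clusters(two, 1L), 2)
  abut <- c(stranded("chr1", 100, 129, "+", 1L),
            stranded("chr1", 130, 159, "+", 1L))
  expect_length(call_clusters(abut, 1L), 2)

  # opposite strands never join
  anti <- c(stranded("chr1", 100, 129, "+", 1L),
            stranded("chr1", 110, 139, "-", 1L))
  cl_anti <- call_clusters(anti, 1L)
  expect_length(cl_anti, 2)
  expect_equal(mcols(cl_anti)$ph, c(1L, 1L))
})

test_that("cluster calling matches the union-find oracle and conserves tags", {
  cfg <- small_config(seed = 29L)
  sim <- simulate_genome(cfg)
  pl <- plant_sites(sim$genome, sim$transcripts, cfg)
  tags <- collapse_duplicates(simulate_tags(pl$truth, cfg))
  expect_gt(length(tags), 300)
  cl <- call_clusters(tags, cfg$n_replicates)

  got <- data.frame(chrom = as.character(seqnames(cl)),
                    start = start(cl), end = end(cl),
                    strand = as.character(strand(cl)),
                    n_tags = mcols(cl)$total_tags)
  got <- got[order(got$chrom, got$start, got$strand), , drop = FALSE]
  want <- oracle_unionfind_clusters(tags)
  expect_equal(got, want, ignore_attr = TRUE)

  # every unique tag belongs to exactly one cluster
  expect_equal(sum(mcols(cl)$total_tags), length(tags))
  expect_true(all(mcols(cl)$bc >= 1 &
                    mcols(cl)$bc <= cfg$n_replicates))
  expect_true(all(mcols(cl)$ph >= 1 &
                    mcols(cl)$ph <= mcols(cl)$total_tags))
})

test_that("BC/PH filtering is monotone and reports pass percentages", {
  cfg <- small_config(seed = 31L)
  sim <- simulate_genome(cfg)
  pl <- plant_sites(sim$genome, sim$transcripts, cfg)
  tags <- collapse_duplicates(simulate_tags(pl$truth, cfg))
  cl <- call_clusters(tags, cfg$n_replicates)

  all_kept <- filter_clusters(cl, min_bc = 1L, min_ph = 1L)
  expect_length(all_kept, length(cl))
  expect_equal(attr(all_kept, "pass_percent"), 100L)

  n_prev <- length(cl) + 1L
  for (bc in 1:3) {
    kept <- length(filter_clusters(cl, min_bc = bc, min_ph = 1L))
    expect_lte(kept, n_prev)
    n_prev <- kept
  }
  n_prev <- length(cl) + 1L
  for (ph in c(1L, 5L, 10L, 20L)) {
    kept <- length(filter_clusters(cl, min_bc = 2L, min_ph = ph))
    expect_lte(kept, n_prev)
    n_prev <- kept
  }
  expect_error(filter_clusters(cl, min_bc = 4L, n_replicates = 3L),
               "replicates")
})

test_that("tag tallies sum per-replicate unique counts", {
  expect_equal(tally_tags(c(5L))$total, 5L)
  expect_error(tally_tags(integer(0)), "replicate")
  tags <- random_tags(200, seed = 41)
  uniq <- collapse_duplicates(tags)
  tl <- tally_tags(unique_tag_counts(uniq))
  expect_equal(tl$total, length(uniq))
})

test_that("cluster tables export as BED6 plus sidecar", {
  tags <- c(stranded("chr1", 100, 129, "+", 1L),
            stranded("chr1", 110, 139, "+", 2L))
  cl <- call_clusters(tags, 2L)
  bed <- withr::local_tempfile(fileext = ".bed")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_table(cl, bed, tsv)
  back <- read_tag_table(bed)
  expect_equal(granges(back), granges(cl), ignore_attr = TRUE)
  side <- read.delim(tsv)
  expect_equal(side$ph, mcols(cl)$ph)
  expect_equal(side$rep1 + side$rep2, mcols(cl)$total_tags)
})
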