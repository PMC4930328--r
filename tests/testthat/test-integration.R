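make_results <- function(event_id, delta_i, fdr) {
  data.frame(event_id = event_id, delta_i = delta_i, fdr = fdr,
             p_value = fdr, tested = !is.na(fdr),
             stringsAsFactors = FALSE)
}

test_that("target calls require significance plus a YCAY-bearing cluster", {
  dna <- paste(rep("G", 1000), collapse = "")
  substr(dna, 560, 563) <- "TCAT"  # UCAU on the plus strand
  genome <- Biostrings::DNAStringSet(c(chr1 = dna))
  events <- data.frame(
    event_id = "e1", gene_id = "g1", chrom = "chr1", strand = "+",
    exon_start = 401L, exon_end = 500L,
    up_intron_start = 201L, up_intron_end = 400L,
    down_intron_start = 501L, down_intron_end = 700L,
    stringsAsFactors = FALSE)
  res <- make_results("e1", 0.4, 0.01)

  ycay_cluster <- stranded("chr1", 550, 600, "+")
  mcols(ycay_cluster)$cluster_id <- "clA"
  poly_g <- stranded("chr1", 420, 460, "+")
  mcols(poly_g)$cluster_id <- "clB"

  # overlapping cluster without YCAY does not support a target
  t0 <- define_targets(res, poly_g, events, genome)
  expect_equal(nrow(t0), 0)

  t1 <- define_targets(res, c(poly_g, ycay_cluster), events, genome)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$direction, "enhanced")
  expect_equal(t1$supporting_clusters, "clA")
  expect_equal(t1$support_regions, "downstream_intron")

  # antisense cluster never supports
  anti <- stranded("chr1", 550, 600, "-")
  mcols(anti)$cluster_id <- "clC"
  expect_equal(nrow(define_targets(res, anti, events, genome)), 0)

  # non-significant events are never targets
  expect_equal(nrow(define_targets(make_results("e1", 0.05, 0.01),
                                   ycay_cluster, events, genome)), 0)
  expect_equal(nrow(define_targets(make_results("e1", 0.4, 0.5),
                                   ycay_cluster, events, genome)), 0)
  # tightening delta_min shrinks the target set
  expect_equal(nrow(define_targets(res, ycay_cluster, events, genome,
                                   delta_min = 0.5)), 0)
})

test_that("rna_map bins, normalises per event and flips minus-strand events", {
  ev <- data.frame(event_id = "e1", chrom = "chr1", strand = "+",
                   exon_start = 2000L, exon_end = 2149L,
                   direction = "enhanced", stringsAsFactors = FALSE)
  # single 20-nt tag fully inside the first upstream-flank bin
  tag <- stranded("chr1", 1000, 1019, "+", 1L)
  prof <- rna_map(tag, ev, intron_flank = 1000L, exon_flank = 50L)
  expect_equal(sum(prof$density), 1)
  expect_equal(prof$density[1], 1)
  expect_true(all(prof$density[-1] == 0))
  expect_equal(nrow(prof), 2 * (1000 + 50) / 25)

  # the same geometry mirrored to the minus strand lands in the same
  # transcript-orientation bin
  ev_m <- data.frame(event_id = "e1", chrom = "chr1", strand = "-",
                     exon_start = 2000L, exon_end = 2149L,
                     direction = "enhanced", stringsAsFactors = FALSE)
  tag_m <- stranded("chr1", 3130, 3149, "-", 1L)
  prof_m <- rna_map(tag_m, ev_m, intron_flank = 1000L,
                    exon_flank = 50L)
  expect_equal(prof_m$density[1], 1)

  # uniform tags over many events give a flat profile
  set.seed(81)
  n_ev <- 80
  ev_many <- data.frame(
    event_id = sprintf("e%02d", seq_len(n_ev)), chrom = "chr1",
    strand = "+",
    exon_start = seq_len(n_ev) * 5000L + 2000L,
    direction = "enhanced", stringsAsFactors = FALSE)
  ev_many$exon_end <- ev_many$exon_start + 149L
  utags <- stranded("chr1", starts <- sample(430000L, 50000L,
                                             replace = TRUE),
                    starts + 29L, "+", 1L)
  flat <- rna_map(utags, ev_many)
  expect_lt(max(flat$density) / min(flat$density), 1.5)
  # profile is invariant to event input order
  flat2 <- rna_map(utags, ev_many[sample(n_ev), ])
  expect_equal(flat2$density, flat$density)

  # a direction with no covered events is dropped with a warning
  ev_empty <- ev
  ev_empty$direction <- "silenced"
  ev_empty$exon_start <- 200000L
  ev_empty$exon_end <- 200149L
  expect_warning(rna_map(tag, rbind(ev, ev_empty)), "silenced")
})

test_that("delta-I correlation matches the closed-form Pearson sum", {
  a <- make_results(c("e1", "e2", "e3"), c(0.1, 0.2, 0.4),
                    c(0.01, 0.01, 0.01))
  expect_equal(delta_i_correlation(a, a)$r, 1)
  b <- a
  b$delta_i <- -a$delta_i
  expect_equal(delta_i_correlation(a, b)$r, -1)
  b$delta_i <- c(0.2, 0.1, 0.3)
  out <- delta_i_correlation(a, b)
  expect_equal(out$n_shared, 3)
  expect_equal(out$r, 0.654653670707977, tolerance = 1e-12)
  # scaling both vectors by the same positive factor leaves r unchanged
  a2 <- a; b2 <- b
  a2$delta_i <- a$delta_i * 2.5
  b2$delta_i <- b$delta_i * 2.5
  expect_equal(delta_i_correlation(a2, b2)$r, out$r)
  expect_error(delta_i_correlation(a[1:2, ], b[1:2, ]), "3")
})

test_that("shared significant-event counts match a brute-force scan", {
  a <- make_results(c("e1", "e2", "e3"), c(0.4, 0.05, -0.3),
                    c(0.01, 0.01, 0.05))
  b <- make_results(c("e2", "e3", "e4"), c(0.4, -0.2, 0.2),
                    c(0.01, 0.01, 0.01))
  out <- shared_event_count(a, b)
  expect_equal(out$n_sig_a, 2)  # e1, e3
  expect_equal(out$n_shared, 1)  # e3

  disj <- shared_event_count(a, make_results("e9", 0.5, 0.01))
  expect_equal(disj$n_shared, 0)

  # degenerate thresholds in B reduce sharing to "tested in B"
  loose <- shared_event_count(a, b, delta_min_b = 0, fdr_max_b = 1.01)
  expect_equal(loose$n_shared, 1)

  set.seed(91)
  ra <- make_results(sprintf("e%03d", 1:200),
                     runif(200, -0.5, 0.5), runif(200))
  rb <- make_results(sprintf("e%03d", sample(300, 200)),
                     runif(200, -0.5, 0.5), runif(200))
  got <- shared_event_count(ra, rb)
  sig <- function(r) r$event_id[abs(r$delta_i) >= 0.1 & r$fdr < 0.1]
  expect_equal(got$n_sig_a, length(sig(ra)))
  expect_equal(got$n_shared, length(intersect(sig(ra), sig(rb))))
})

test_that("the one-call pipeline chains every stage and writes its report", {
  cfg <- small_config(seed = 47L, inclusion_wt = 0.8,
                      inclusion_ko = 0.4)
  out_dir <- withr::local_tempdir()
  run <- run_pipeline(cfg, out_dir = out_dir)
  expect_gt(length(run$bc_clusters), 0)
  expect_equal(sum(run$splicing$tested), cfg$n_genes)
  expect_gt(nrow(run$targets), 0)
  expect_true(all(abs(run$targets$delta_i) >= 0.1 &
                    run$targets$fdr < 0.1))
  expect_true(file.exists(file.path(out_dir, "report.txt")))
  expect_true(file.exists(file.path(out_dir, "targets.tsv")))
  rep_lines <- readLines(file.path(out_dir, "report.txt"))
  expect_true(any(grepl("unique tags total", rep_lines)))
})
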