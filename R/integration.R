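# Integration of clusters, motifs and splicing results: regulated
# target-exon calls, RNA-map metagene profiles, cross-genotype delta-I
# correlation, and a one-call pipeline over the synthetic generators.

.event_region_granges <- function(events, which = c("alt_exon",
                                                    "upstream_intron",
                                                    "downstream_intron")) {
  which <- match.arg(which)
  s <- switch(which, alt_exon = events$exon_start,
              upstream_intron = events$up_intron_start,
              downstream_intron = events$down_intron_start)
  e <- switch(which, alt_exon = events$exon_end,
              upstream_intron = events$up_intron_end,
              downstream_intron = events$down_intron_end)
  GRanges(events$chrom, IRanges(s, e), strand = events$strand)
}

#' Call regulated target events from splicing, binding and motif evidence
#'
#' An event is a target iff it passes `|delta_i| >= delta_min` and
#' `fdr < fdr_max`, and at least one cluster overlaps (>= 1 nt, same
#' strand) its alternative exon or either full flanking intron while
#' containing >= 1 YCAY match in its strand-matched sequence. Direction
#' is `enhanced` for `delta_i > 0` and `silenced` for `delta_i < 0`.
#'
#' @param splicing_results Data frame from [splicing_table()].
#' @param clusters Stranded cluster `GRanges` (already BC-filtered) with
#'   a `cluster_id` metadata column.
#' @param events Event data frame (as in `truth$events`) with columns
#'   `event_id`, `gene_id`, `chrom`, `strand`, `exon_start`, `exon_end`,
#'   `up_intron_start/end`, `down_intron_start/end`.
#' @param genome A named `DNAStringSet` (for the YCAY check).
#' @param delta_min,fdr_max Significance thresholds (defaults 0.1, 0.1).
#' @return A data frame of targets: `event_id`, `gene_id`, `delta_i`,
#'   `fdr`, `direction`, `supporting_clusters`, `support_regions`
#'   (comma-separated), with attributes `n_events` and `n_genes`.
#' @export
define_targets <- function(splicing_results, clusters, events, genome,
                           delta_min = 0.1, fdr_max = 0.1) {
  res <- merge(splicing_results, events, by = "event_id",
               suffixes = c("", ".ev"))
  sig <- !is.na(res$fdr) & abs(res$delta_i) >= delta_min &
    res$fdr < fdr_max
  res <- res[sig, , drop = FALSE]
  gene_col <- if (!is.null(res$gene_id)) res$gene_id else res$gene_id.ev

  has_ycay <- if (length(clusters)) {
    vapply(cluster_sequences(clusters, genome),
           function(s) length(ycay_scan(s)) > 0L, logical(1L))
  } else logical(0)

  rows <- list()
  region_names <- c("alt_exon", "upstream_intron", "downstream_intron")
  if (nrow(res)) {
    support <- vector("list", nrow(res))
    for (rn in region_names) {
      reg <- .event_region_granges(res, rn)
      hits <- findOverlaps(reg, clusters, minoverlap = 1L)
      keep <- has_ycay[subjectHits(hits)]
      hits <- hits[keep]
      for (k in seq_along(hits)) {
        i <- queryHits(hits)[k]
        support[[i]] <- rbind(support[[i]], data.frame(
          cluster_id = mcols(clusters)$cluster_id[subjectHits(hits)[k]],
          region = rn, stringsAsFactors = FALSE))
      }
    }
    for (i in seq_len(nrow(res))) {
      sup <- support[[i]]
      if (is.null(sup)) next
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = res$event_id[i], gene_id = gene_col[i],
        delta_i = res$delta_i[i], fdr = res$fdr[i],
        direction = if (res$delta_i[i] > 0) "enhanced" else "silenced",
        supporting_clusters = paste(unique(sup$cluster_id),
                                    collapse = ","),
        support_regions = paste(unique(sup$region), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = character(0), gene_id = character(0),
               delta_i = numeric(0), fdr = numeric(0),
               direction = character(0),
               supporting_clusters = character(0),
               support_regions = character(0),
               stringsAsFactors = FALSE)
  attr(out, "n_events") <- nrow(out)
  attr(out, "n_genes") <- length(unique(out$gene_id))
  out
}

#' RNA-map metagene profile of CLIP tag density around cassette exons
#'
#' For each event, strand-matched tag coverage is collected over two
#' composite segments in transcript orientation: around the exon start
#' (`intron_flank` nt of upstream intron plus `exon_flank` nt of exon)
#' and around the exon end (`exon_flank` nt of exon plus `intron_flank`
#' nt of downstream intron). Coverage is summed in `bin_width`-nt
#' windows, normalised per event by its total tag coverage (events with
#' none are dropped), and averaged within each direction set.
#'
#' @param tags Unique tag `GRanges` (from [collapse_duplicates()]).
#' @param events Event data frame with a `direction` column partitioning
#'   events (e.g. `enhanced` / `silenced`).
#' @param intron_flank,exon_flank Segment extents in nt (defaults 1000
#'   and 50); both must be multiples of `bin_width`.
#' @param bin_width Window size in nt (default 25).
#' @return A data frame with columns `direction`, `bin`, `offset` (the
#'   bin's 5' edge relative to the exon start for the first segment and
#'   the exon end for the second, in transcript coordinates), `segment`
#'   (`exon_start` / `exon_end`) and `density`; attribute `n_events`
#'   gives the events retained per direction. Directions with no usable
#'   events are omitted with a warning.
#' @export
rna_map <- function(tags, events, intron_flank = 1000L,
                    exon_flank = 50L, bin_width = 25L) {
  if (intron_flank %% bin_width != 0L || exon_flank %% bin_width != 0L)
    stop("flanks must be multiples of bin_width", call. = FALSE)
  if (is.null(events$direction))
    stop("events must carry a 'direction' column", call. = FALSE)
  seg_len <- intron_flank + exon_flank
  n_bins_seg <- seg_len %/% bin_width
  n_bins <- 2L * n_bins_seg
  cov_by_strand <- list("+" = coverage(tags[strand(tags) == "+"]),
                        "-" = coverage(tags[strand(tags) == "-"]))

  window_cov <- function(cov_list, chrom, lo, hi) {
    n <- hi - lo + 1L
    v <- numeric(n)
    rle <- cov_list[[chrom]]
    if (is.null(rle)) return(v)
    clo <- max(1L, lo)
    chi <- min(length(rle), hi)
    if (chi >= clo)
      v[(clo - lo + 1L):(chi - lo + 1L)] <-
        as.numeric(rle[clo:chi])
    v
  }

  profiles <- list()
  n_events <- c()
  for (dir in unique(events$direction)) {
    ev <- events[events$direction == dir, , drop = FALSE]
    acc <- numeric(n_bins)
    kept <- 0L
    for (i in seq_len(nrow(ev))) {
      w1 <- c(ev$exon_start[i] - intron_flank,
              ev$exon_start[i] + exon_flank - 1L)
      w2 <- c(ev$exon_end[i] - exon_flank + 1L,
              ev$exon_end[i] + intron_flank)
      v1 <- window_cov(cov_by_strand[[ev$strand[i]]], ev$chrom[i],
                       w1[1L], w1[2L])
      v2 <- window_cov(cov_by_strand[[ev$strand[i]]], ev$chrom[i],
                       w2[1L], w2[2L])
      if (ev$strand[i] == "-") {
        tmp <- rev(v2)
        v2 <- rev(v1)
        v1 <- tmp
      }
      v <- c(v1, v2)
      s <- sum(v)
      if (s == 0) next
      binned <- rowsum(v, rep(seq_len(n_bins), each = bin_width))[, 1L]
      acc <- acc + binned / s
      kept <- kept + 1L
    }
    if (kept == 0L) {
      warning("no events with tag coverage for direction '", dir, "'",
              call. = FALSE)
      next
    }
    offs <- c(seq(-intron_flank, exon_flank - bin_width, by = bin_width),
              seq(-exon_flank, intron_flank - bin_width, by = bin_width))
    profiles[[dir]] <- data.frame(
      direction = dir, bin = seq_len(n_bins), offset = offs,
      segment = rep(c("exon_start", "exon_end"), each = n_bins_seg),
      density = acc / kept, stringsAsFactors = FALSE)
    n_events[dir] <- kept
  }
  out <- do.call(rbind, c(profiles, list(make.row.names = FALSE)))
  attr(out, "n_events") <- n_events
  out
}

#' Correlation of delta-I between two result tables
#'
#' Pearson correlation of paired delta-I values over events tested in
#' both tables.
#'
#' @param results_a,results_b Data frames from [splicing_table()].
#' @return A list with `r` and `n_shared`.
#' @export
delta_i_correlation <- function(results_a, results_b) {
  a <- results_a[results_a$tested & !is.na(results_a$delta_i), ]
  b <- results_b[results_b$tested & !is.na(results_b$delta_i), ]
  shared <- intersect(a$event_id, b$event_id)
  if (length(shared) < 3L)
    stop("fewer than 3 shared tested events", call. = FALSE)
  x <- a$delta_i[match(shared, a$event_id)]
  y <- b$delta_i[match(shared, b$event_id)]
  list(r = cor(x, y, method = "pearson"), n_shared = length(shared))
}

#' Count events significant in one table and shared with another
#'
#' @param results_a,results_b Data frames from [splicing_table()].
#' @param delta_min_a,fdr_max_a,delta_min_b,fdr_max_b Per-table
#'   significance thresholds.
#' @return A list with `n_sig_a` (events significant in A) and
#'   `n_shared` (significant in both).
#' @export
shared_event_count <- function(results_a, results_b,
                               delta_min_a = 0.1, fdr_max_a = 0.1,
                               delta_min_b = 0.1, fdr_max_b = 0.1) {
  sig <- function(res, dmin, fmax) {
    res$event_id[!is.na(res$fdr) & abs(res$delta_i) >= dmin &
                   res$fdr < fmax]
  }
  sa <- sig(results_a, delta_min_a, fdr_max_a)
  sb <- sig(results_b, delta_min_b, fdr_max_b)
  list(n_sig_a = length(sa), n_shared = length(intersect(sa, sb)))
}

#' Run the full synthetic-data pipeline
#'
#' Chains the generators and every analysis stage: simulate genome and
#' annotation, plant binding sites, simulate replicate CLIP tags and
#' two-genotype junction counts, collapse duplicates, call and filter
#' clusters, rank tetramer enrichment against shuffled controls, assign
#' genomic regions, quantify splicing, call targets, and build the
#' RNA-map profile of significant events. Optionally writes every
#' interface file plus a plain-text run report.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory for output files.
#' @param min_bc,min_ph Cluster filter for the working (BC2) set.
#' @param min_total_reads Low-expression filter for splicing.
#' @param delta_min,fdr_max Target significance thresholds.
#' @param n_shuffles Shuffled control sets for motif enrichment.
#' @return A list with all intermediate and final objects: `genome`,
#'   `transcripts`, `truth`, `tags`, `unique_tags`, `clusters`,
#'   `bc_clusters`, `enrichment`, `region_fractions`, `junctions`,
#'   `splicing`, `targets`, `profile`, `tag_tally`.
#' @export
run_pipeline <- function(config, out_dir = NULL, min_bc = 2L,
                         min_ph = 1L, min_total_reads = 20L,
                         delta_min = 0.1, fdr_max = 0.1,
                         n_shuffles = 20L) {
  sim <- simulate_genome(config)
  planted <- plant_sites(sim$genome, sim$transcripts, config)
  genome <- planted$genome
  truth <- planted$truth
  tags <- simulate_tags(truth, config)
  junctions <- simulate_junctions(truth, config)

  uniq <- collapse_duplicates(tags)
  clusters <- call_clusters(uniq, n_replicates = config$n_replicates)
  bc_clusters <- filter_clusters(clusters, min_bc = min_bc,
                                 min_ph = min_ph,
                                 n_replicates = config$n_replicates)
  tag_tally <- tally_tags(unique_tag_counts(uniq))

  seqs <- cluster_sequences(bc_clusters, genome)
  enrichment <- NULL
  if (length(seqs)) {
    ctrl <- lapply(shuffle_controls(seqs, n_shuffles = n_shuffles,
                                    seed = config$seed),
                   count_tetramers)
    enrichment <- rank_enrichment(count_tetramers(seqs), ctrl)
  }
  region_fractions <- if (length(bc_clusters))
    region_distribution(bc_clusters, sim$transcripts) else NULL

  splicing <- splicing_table(truth$events, junctions,
                             min_total_reads = min_total_reads)
  targets <- define_targets(splicing, bc_clusters, truth$events, genome,
                            delta_min = delta_min, fdr_max = fdr_max)

  sig <- !is.na(splicing$fdr) & abs(splicing$delta_i) >= delta_min &
    splicing$fdr < fdr_max
  profile <- NULL
  if (any(sig)) {
    ev <- merge(truth$events, splicing[sig, c("event_id", "delta_i")],
                by = "event_id")
    ev$direction <- ifelse(ev$delta_i > 0, "enhanced", "silenced")
    profile <- suppressWarnings(rna_map(uniq, ev))
  }

  out <- list(genome = genome, transcripts = sim$transcripts,
              truth = truth, tags = tags, unique_tags = uniq,
              clusters = clusters, bc_clusters = bc_clusters,
              enrichment = enrichment,
              region_fractions = region_fractions,
              junctions = junctions, splicing = splicing,
              targets = targets, profile = profile,
              tag_tally = tag_tally, config = config)
  if (!is.null(out_dir)) .write_pipeline_outputs(out, out_dir)
  out
}

.write_pipeline_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_genome(run$genome, p("genome.fa"))
  write_annotation(run$transcripts, p("annotation.gtf"))
  for (r in unique(mcols(run$tags)$replicate))
    write_tag_table(run$tags[mcols(run$tags)$replicate == r],
                    p(sprintf("tags_rep%d.bed", r)))
  write_cluster_table(run$clusters, p("clusters.bed"),
                      p("clusters.tsv"))
  write_junction_table(run$junctions, p("junctions.tsv"))
  write_splicing_table(run$splicing, p("splicing.tsv"))
  if (!is.null(run$enrichment))
    write.table(run$enrichment, p("tetramer_enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(run$targets, p("targets.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(run$profile))
    write.table(run$profile, p("rna_map.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  writeLines(pipeline_report(run), p("report.txt"))
  invisible(out_dir)
}

#' Plain-text report of a pipeline run
#'
#' @param run A list from [run_pipeline()].
#' @return Character vector of report lines.
#' @export
pipeline_report <- function(run) {
  cfg <- run$config
  tally <- run$tag_tally
  sig_n <- attr(run$targets, "n_events")
  c("clipmap run report",
    sprintf("seed: %d", cfg$seed),
    sprintf("replicates: %d", cfg$n_replicates),
    sprintf("unique tags per replicate: %s",
            paste(tally$per_replicate, collapse = ", ")),
    sprintf("unique tags total: %d", tally$total),
    sprintf("clusters: %d", length(run$clusters)),
    sprintf("BC>=2 clusters: %d (%s%% of all)",
            length(run$bc_clusters),
            attr(run$bc_clusters, "pass_percent")),
    sprintf("events tested: %d", sum(run$splicing$tested)),
    sprintf("target events: %d on %d genes", sig_n,
            attr(run$targets, "n_genes")))
}
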