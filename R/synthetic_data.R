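# Synthetic-data generator: toy genome and annotation, planted YCAY-rich
# binding sites, replicate CLIP tags with PCR duplicates, and two-genotype
# cassette-exon junction counts with known ground truth.
#
# Each generator draws from its own RNG stream, seeded from config$seed by
# a fixed offset, so adding or re-running one generator never perturbs the
# others.

.SEED_GENOME <- 0L
.SEED_SITES <- 1L
.SEED_TAGS <- 2L
.SEED_JUNCTIONS <- 3L

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. The defaults
#' describe the study conditions the rest of the package is validated
#' under: three biological replicates, a mean of 8 CLIP tags per planted
#' site per replicate over a background of 0.5 tags/kb/replicate, 30-nt
#' tags, and junction sequencing depth of ~100 reads per event per
#' replicate per genotype.
#'
#' @param seed Integer seed; identical seeds give bit-identical outputs.
#' @param n_chroms,chrom_length Number and length (nt) of chromosomes.
#' @param n_genes Number of genes, tiled without overlap across
#'   chromosomes on alternating strands.
#' @param exons_per_gene Exons per gene (>= 3 so cassette events exist).
#' @param exon_length,intron_length,intergenic_length Gene geometry (nt).
#' @param n_sites Number of planted binding sites; sites are placed in
#'   genes `1..n_sites` (one per gene), so ground-truth "bound" status is
#'   deterministic.
#' @param site_motif_copies Tandem YCAY copies written at each site.
#' @param site_exon_frac Fraction of sites planted in the cassette exon;
#'   the remainder go to the downstream flanking intron.
#' @param tags_per_site_mean Expected CLIP tags per site per replicate
#'   (Poisson).
#' @param background_tag_rate Background tags per kb of transcribed
#'   sequence per replicate (Poisson).
#' @param n_replicates Number of biological replicates.
#' @param pcr_duplication_rate Probability that a tag is emitted a second
#'   time at identical coordinates.
#' @param tag_length Tag length (nt).
#' @param tag_jitter Uniform start jitter around the site start (+/- nt).
#' @param junction_depth Expected junction reads per event per replicate
#'   per genotype (Poisson).
#' @param inclusion_wt,inclusion_ko True inclusion ratios per event in
#'   `[0,1]`; scalars are recycled across all events, vectors must have
#'   length `n_genes`.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, n_chroms = 2L,
                              chrom_length = 250000L, n_genes = 60L,
                              exons_per_gene = 3L, exon_length = 150L,
                              intron_length = 1200L,
                              intergenic_length = 500L, n_sites = 40L,
                              site_motif_copies = 3L,
                              site_exon_frac = 0.2,
                              tags_per_site_mean = 8,
                              background_tag_rate = 0.5,
                              n_replicates = 3L,
                              pcr_duplication_rate = 0.15,
                              tag_length = 30L, tag_jitter = 10L,
                              junction_depth = 100,
                              inclusion_wt = 0.5, inclusion_ko = 0.5) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              intergenic_length = as.integer(intergenic_length),
              n_sites = as.integer(n_sites),
              site_motif_copies = as.integer(site_motif_copies),
              site_exon_frac = site_exon_frac,
              tags_per_site_mean = tags_per_site_mean,
              background_tag_rate = background_tag_rate,
              n_replicates = as.integer(n_replicates),
              pcr_duplication_rate = pcr_duplication_rate,
              tag_length = as.integer(tag_length),
              tag_jitter = as.integer(tag_jitter),
              junction_depth = junction_depth,
              inclusion_wt = inclusion_wt,
              inclusion_ko = inclusion_ko)
  rates <- c(cfg$tags_per_site_mean, cfg$background_tag_rate,
             cfg$junction_depth, cfg$pcr_duplication_rate)
  if (any(rates < 0)) stop("all rates must be >= 0", call. = FALSE)
  if (cfg$pcr_duplication_rate > 1)
    stop("pcr_duplication_rate must be in [0,1]", call. = FALSE)
  for (f in c("inclusion_wt", "inclusion_ko")) {
    v <- cfg[[f]]
    if (any(v < 0 | v > 1))
      stop(f, " values must lie in [0,1]", call. = FALSE)
    if (!length(v) %in% c(1L, cfg$n_genes))
      stop(f, " must be scalar or length n_genes", call. = FALSE)
  }
  if (cfg$exons_per_gene < 3L && cfg$n_genes > 0L)
    stop("exons_per_gene must be >= 3 so cassette events exist",
         call. = FALSE)
  if (cfg$n_sites > cfg$n_genes)
    stop("n_sites must not exceed n_genes", call. = FALSE)
  if (cfg$site_exon_frac < 0 || cfg$site_exon_frac > 1)
    stop("site_exon_frac must be in [0,1]", call. = FALSE)
  structure(cfg, class = "sim_config")
}

.gene_length <- function(cfg) {
  cfg$exons_per_gene * cfg$exon_length +
    (cfg$exons_per_gene - 1L) * cfg$intron_length
}

#' Simulate a toy genome and annotation
#'
#' Generates uniform-random chromosome sequences and tiles `n_genes`
#' non-overlapping genes across them on alternating strands. Each gene has
#' `exons_per_gene` exons so a cassette event (the second exon in
#' transcript orientation) exists, and a CDS leaving 50-nt UTRs at both
#' transcript ends.
#'
#' @param config A [simulation_config()].
#' @return A list with `genome` (`DNAStringSet`) and `transcripts`
#'   (`TranscriptModels`).
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed + .SEED_GENOME)
  chrom_names <- paste0("chr", seq_len(config$n_chroms))
  genome <- DNAStringSet(vapply(chrom_names, function(chr) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length,
                 replace = TRUE), collapse = "")
  }, character(1L)))
  names(genome) <- chrom_names

  glen <- .gene_length(config)
  per_chrom <- max(0L, (config$chrom_length - config$intergenic_length) %/%
                     (glen + config$intergenic_length))
  if (config$n_genes > per_chrom * config$n_chroms)
    stop("genes do not fit in chrom_length: at most ",
         per_chrom * config$n_chroms, " genes fit", call. = FALSE)

  g <- seq_len(config$n_genes)
  chrom_i <- ((g - 1L) %/% per_chrom) + 1L
  slot <- (g - 1L) %% per_chrom
  gstart <- config$intergenic_length + 1L +
    slot * (glen + config$intergenic_length)
  strand_chr <- ifelse(g %% 2L == 1L, "+", "-")
  k <- config$exons_per_gene
  ex_off <- (seq_len(k) - 1L) * (config$exon_length +
                                   config$intron_length)
  ex_all <- GRanges(rep(chrom_names[chrom_i], each = k),
                    IRanges(rep(gstart, each = k) + rep(ex_off,
                                                        config$n_genes),
                            width = config$exon_length),
                    strand = rep(strand_chr, each = k))
  ex_list <- split(ex_all, rep(g, each = k))
  models <- lapply(g, function(i) {
    exons <- ex_list[[i]]
    if (strand_chr[i] == "-") exons <- rev(exons)
    gid <- sprintf("g%04d", i)
    structure(list(transcript_id = paste0(gid, ".t1"), gene_id = gid,
                   strand = strand_chr[i], exons = exons,
                   cds_start = gstart[i] + 50L,
                   cds_end = gstart[i] + glen - 1L - 50L),
              class = "TranscriptModel")
  })
  list(genome = genome,
       transcripts = structure(models, class = "TranscriptModels"))
}

#' Plant YCAY-rich binding sites and define event-level ground truth
#'
#' Overwrites the genome at each site with `site_motif_copies` tandem
#' YCAY instances (each Y drawn from `{C,U}`, written as C/T on the
#' genome respecting the gene's strand). Sites are placed one per gene in
#' genes `1..n_sites`, inside the cassette exon with probability
#' `site_exon_frac` and otherwise in the proximal downstream flanking
#' intron (100-400 nt from its 5' end in transcript orientation, where
#' position-dependent splicing regulators concentrate inclusion-enhancing
#' binding). Per-event true inclusion ratios come from
#' `inclusion_wt`/`inclusion_ko`.
#'
#' @param genome A `DNAStringSet` from [simulate_genome()].
#' @param transcripts The matching `TranscriptModels`.
#' @param config The same [simulation_config()].
#' @return A list with the modified `genome` and `truth`, where `truth`
#'   (class `clip_truth`) holds `sites` (`GRanges` with `gene_id`,
#'   `region`, `rna`), `events` (one cassette event per gene with true
#'   inclusion and delta-I), and `gene_spans` (`GRanges`).
#' @export
plant_sites <- function(genome, transcripts, config) {
  set.seed(config$seed + .SEED_SITES)
  events <- .cassette_events(transcripts, config)
  site_len <- 4L * config$site_motif_copies

  sites <- GRanges()
  rna_strings <- character(0)
  if (config$n_sites > 0L) {
    rows <- events[seq_len(config$n_sites), , drop = FALSE]
    in_exon <- runif(config$n_sites) < config$site_exon_frac
    site_start <- integer(config$n_sites)
    for (i in seq_len(config$n_sites)) {
      if (in_exon[i]) {
        lo <- rows$exon_start[i] + 10L
        hi <- rows$exon_end[i] - site_len - 10L
        if (hi < lo)
          stop("insufficient space to place site in gene ",
               rows$gene_id[i], call. = FALSE)
        site_start[i] <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      } else {
        # proximal downstream intron (100-400 nt from its 5' end in
        # transcript orientation), where position-dependent regulators
        # such as NOVA concentrate their inclusion-enhancing binding
        max_off <- min(400L,
                       rows$down_intron_end[i] -
                         rows$down_intron_start[i] + 1L -
                         site_len - 100L)
        if (max_off < 100L)
          stop("insufficient space to place site in gene ",
               rows$gene_id[i], call. = FALSE)
        off <- 100L + sample.int(max_off - 100L + 1L, 1L) - 1L
        site_start[i] <- if (rows$strand[i] == "+")
          rows$down_intron_start[i] + off else
          rows$down_intron_end[i] - off - site_len + 1L
      }
    }
    ys <- matrix(sample(c("C", "U"), 2L * config$site_motif_copies *
                          config$n_sites, replace = TRUE),
                 nrow = config$n_sites)
    rna_strings <- apply(ys, 1L, function(y) {
      paste(vapply(seq_len(config$site_motif_copies), function(k) {
        paste0(y[2L * k - 1L], "CA", y[2L * k])
      }, character(1L)), collapse = "")
    })
    sites <- GRanges(rows$chrom, IRanges(site_start, width = site_len),
                     strand = rows$strand)
    mcols(sites)$gene_id <- rows$gene_id
    mcols(sites)$region <- ifelse(in_exon, "alt_exon", "downstream_intron")
    mcols(sites)$rna <- rna_strings
    dna <- DNAStringSet(chartr("U", "T", rna_strings))
    neg <- rows$strand == "-"
    if (any(neg)) dna[neg] <- reverseComplement(dna[neg])
    for (chr in unique(rows$chrom)) {
      sel <- rows$chrom == chr
      genome[[chr]] <- Biostrings::replaceAt(
        genome[[chr]], ranges(sites)[sel], dna[sel])
    }
    events$bound <- events$gene_id %in% rows$gene_id
  } else {
    events$bound <- logical(nrow(events))
  }

  spans <- vapply(transcripts, function(m)
    c(min(start(m$exons)), max(end(m$exons))), numeric(2L))
  gene_spans <- GRanges(
    vapply(transcripts, function(m)
      as.character(seqnames(m$exons))[1L], character(1L)),
    IRanges(spans[1L, ], spans[2L, ]),
    strand = vapply(transcripts, `[[`, "", "strand"))
  mcols(gene_spans)$gene_id <- vapply(transcripts, `[[`, "", "gene_id")

  truth <- structure(list(sites = sites, events = events,
                          gene_spans = gene_spans),
                     class = "clip_truth")
  list(genome = genome, truth = truth)
}

# One cassette event per gene: the second exon in transcript orientation,
# with its flanking introns. Coordinates 1-based closed, genomic; the
# up/down intron labels follow transcript orientation.
.cassette_events <- function(transcripts, config) {
  rows <- lapply(transcripts, function(m) {
    ex <- m$exons  # 5'->3' in transcript orientation
    alt_s <- start(ex)[2L]
    alt_e <- end(ex)[2L]
    if (m$strand == "+") {
      up <- c(end(ex)[1L] + 1L, alt_s - 1L)
      down <- c(alt_e + 1L, start(ex)[3L] - 1L)
    } else {
      up <- c(alt_e + 1L, start(ex)[1L] - 1L)
      down <- c(end(ex)[3L] + 1L, alt_s - 1L)
    }
    data.frame(event_id = paste0(m$gene_id, "_e1"),
               gene_id = m$gene_id,
               chrom = as.character(seqnames(ex))[1L],
               strand = m$strand,
               exon_start = alt_s, exon_end = alt_e,
               up_intron_start = up[1L], up_intron_end = up[2L],
               down_intron_start = down[1L], down_intron_end = down[2L],
               stringsAsFactors = FALSE)
  })
  events <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  events$i_wt <- rep(config$inclusion_wt, length.out = nrow(events))
  events$i_ko <- rep(config$inclusion_ko, length.out = nrow(events))
  events$delta_i_true <- events$i_ko - events$i_wt
  events
}

#' Simulate replicate CLIP tag tables
#'
#' For each replicate, draws `Poisson(tags_per_site_mean)` tags per
#' planted site with uniform start jitter of +/- `tag_jitter` nt, plus
#' Poisson background tags uniform over transcribed (gene-span) regions
#' on the gene's strand. Each tag is then duplicated at identical
#' coordinates with probability `pcr_duplication_rate`, emulating PCR
#' duplicates.
#'
#' @param truth A `clip_truth` from [plant_sites()].
#' @param config The same [simulation_config()].
#' @return A `GRanges` of fixed-length stranded tags with metadata
#'   column `replicate` (integer, 1-based).
#' @export
simulate_tags <- function(truth, config) {
  set.seed(config$seed + .SEED_TAGS)
  sites <- truth$sites
  spans <- truth$gene_spans
  span_w <- width(spans)
  total_kb <- sum(span_w) / 1000
  out <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    parts <- list()
    if (length(sites) && config$tags_per_site_mean > 0) {
      n_per_site <- rpois(length(sites), config$tags_per_site_mean)
      idx <- rep(seq_along(sites), n_per_site)
      if (length(idx)) {
        jit <- sample(seq(-config$tag_jitter, config$tag_jitter),
                      length(idx), replace = TRUE)
        starts <- start(sites)[idx] + jit
        parts$site <- GRanges(seqnames(sites)[idx],
                              IRanges(starts, width = config$tag_length),
                              strand = strand(sites)[idx])
      }
    }
    if (length(spans) && config$background_tag_rate > 0) {
      n_bg <- rpois(1L, config$background_tag_rate * total_kb)
      if (n_bg > 0L) {
        gi <- sample.int(length(spans), n_bg, replace = TRUE,
                         prob = span_w)
        max_off <- pmax(1L, span_w[gi] - config$tag_length + 1L)
        off <- floor(runif(n_bg) * max_off)
        starts <- start(spans)[gi] + off
        parts$bg <- GRanges(seqnames(spans)[gi],
                            IRanges(starts, width = config$tag_length),
                            strand = strand(spans)[gi])
      }
    }
    gr <- if (length(parts)) do.call(c, unname(parts)) else GRanges()
    if (length(gr) && config$pcr_duplication_rate > 0) {
      dup <- runif(length(gr)) < config$pcr_duplication_rate
      gr <- c(gr, gr[dup])
    }
    if (length(gr)) {
      # keep tags inside chromosome bounds without changing their length
      shift_left <- pmax(0L, end(gr) - config$chrom_length)
      gr <- shift(gr, -shift_left)
      shift_right <- pmax(0L, 1L - start(gr))
      gr <- shift(gr, shift_right)
      mcols(gr)$replicate <- rep(r, length(gr))
    } else {
      mcols(gr)$replicate <- integer(0)
    }
    out[[r]] <- gr
  }
  tags <- do.call(c, out)
  tags
}

#' Simulate two-genotype junction-count tables
#'
#' Per event, genotype and replicate, an event coverage `c` is drawn as
#' `Poisson(junction_depth)`; each of the two inclusion junctions is then
#' sampled as `Binomial(c, I_true)` and the exclusion junction as
#' `Binomial(c, 1 - I_true)`, mimicking independent short-read sampling
#' at the three junction positions. Under this model the pooled
#' inclusion estimator `m / (m + excl)` with `m = (up + down) / 2` is
#' unbiased for `I_true`.
#'
#' @param truth A `clip_truth` from [plant_sites()] (only its `events`
#'   component is used).
#' @param config The same [simulation_config()].
#' @return A data frame with columns `event_id`, `genotype` (`WT`/`KO`),
#'   `replicate`, `up_inc`, `down_inc`, `excl`.
#' @export
simulate_junctions <- function(truth, config) {
  set.seed(config$seed + .SEED_JUNCTIONS)
  ev <- truth$events
  grid <- expand.grid(event = seq_len(nrow(ev)),
                      genotype = c("WT", "KO"),
                      replicate = seq_len(config$n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  i_true <- ifelse(grid$genotype == "WT", ev$i_wt[grid$event],
                   ev$i_ko[grid$event])
  depth <- rpois(nrow(grid), config$junction_depth)
  up <- rbinom(nrow(grid), depth, i_true)
  down <- rbinom(nrow(grid), depth, i_true)
  excl <- rbinom(nrow(grid), depth, 1 - i_true)
  data.frame(event_id = ev$event_id[grid$event],
             genotype = grid$genotype, replicate = grid$replicate,
             up_inc = up, down_inc = down, excl = excl,
             stringsAsFactors = FALSE)
}

#' Write a junction-count table as TSV
#' @param junctions Data frame from [simulate_junctions()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_junction_table <- function(junctions, path) {
  write.table(junctions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a junction-count table
#' @param path Path to a TSV with header columns `event_id`, `genotype`,
#'   `replicate`, `up_inc`, `down_inc`, `excl`.
#' @return A data frame.
#' @export
read_junction_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("event_id", "genotype", "replicate", "up_inc", "down_inc",
            "excl")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("junction table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}
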