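# Assignment of clusters to genomic region categories and cross-set
# cluster overlap fractions. Assignment is strand-matched and decided at
# the cluster midpoint; isoform conflicts are resolved by precedence
# exonic > intron > intergenic, and within exonic cds > 5' UTR > 3' UTR.

.REGION_LEVELS <- c("five_prime_utr", "cds", "three_prime_utr",
                    "intron", "intergenic")

# Precedence ranks (lower wins). cds outranks the UTRs per the mutually
# exclusive exon subtotals convention; 5' UTR before 3' UTR is an
# arbitrary deterministic tie-break between isoforms.
.REGION_RANK <- c(cds = 1L, five_prime_utr = 2L, three_prime_utr = 3L,
                  intron = 4L)

# Flattens transcript models into labelled region ranges. Exon bases of
# transcripts without CDS annotation are labelled cds (keeps the label
# set exhaustive without inventing a category).
.region_index <- function(transcripts) {
  pieces <- lapply(transcripts, function(m) {
    ex <- m$exons[order(start(m$exons))]
    introns <- transcript_introns(m)
    out <- list()
    if (is.na(m$cds_start)) {
      lab_ex <- granges(ex)
      mcols(lab_ex)$label <- rep("cds", length(lab_ex))
      out$ex <- lab_ex
    } else {
      cds_part <- restrict(granges(ex), start = as.integer(m$cds_start),
                           end = as.integer(m$cds_end))
      left <- restrict(granges(ex), end = as.integer(m$cds_start) - 1L)
      right <- restrict(granges(ex), start = as.integer(m$cds_end) + 1L)
      # genomic-left of the CDS is the 5' UTR on '+', the 3' UTR on '-'
      lab_left <- if (m$strand == "+") "five_prime_utr" else
        "three_prime_utr"
      lab_right <- if (m$strand == "+") "three_prime_utr" else
        "five_prime_utr"
      for (part in list(list(cds_part, "cds"), list(left, lab_left),
                        list(right, lab_right))) {
        gr <- part[[1L]][width(part[[1L]]) > 0L]
        if (length(gr)) {
          mcols(gr)$label <- rep(part[[2L]], length(gr))
          out[[length(out) + 1L]] <- gr
        }
      }
    }
    if (length(introns)) {
      intr <- granges(introns)
      mcols(intr)$label <- rep("intron", length(intr))
      out$intr <- intr
    }
    do.call(c, unname(out))
  })
  do.call(c, unname(pieces))
}

#' Assign clusters to genomic region categories
#'
#' The label is decided at the cluster anchor (midpoint): an anchor
#' inside an exon is sub-classified by the transcript's CDS bounds
#' (5' UTR / CDS / 3' UTR in transcript orientation); an anchor inside a
#' transcript span but not an exon is intronic; anything else is
#' intergenic. Only same-strand transcripts are considered; antisense
#' overlap is intergenic. Conflicting isoforms resolve by precedence
#' exonic > intron > intergenic and, within exonic, cds > UTR.
#'
#' @param clusters Stranded `GRanges`.
#' @param transcripts A `TranscriptModels` list.
#' @return A factor of region labels, one per cluster, with levels
#'   `five_prime_utr`, `cds`, `three_prime_utr`, `intron`, `intergenic`.
#' @export
assign_region <- function(clusters, transcripts) {
  .check_stranded(clusters, "cluster")
  anchors <- GRanges(seqnames(clusters),
                     IRanges(cluster_anchor(clusters), width = 1L),
                     strand = strand(clusters))
  labels <- rep("intergenic", length(clusters))
  if (length(transcripts)) {
    idx <- .region_index(transcripts)
    hits <- findOverlaps(anchors, idx)
    if (length(hits)) {
      rank <- .REGION_RANK[mcols(idx)$label[subjectHits(hits)]]
      best <- tapply(rank, queryHits(hits), min)
      q <- as.integer(names(best))
      labels[q] <- names(.REGION_RANK)[as.integer(best)]
    }
  }
  factor(labels, levels = .REGION_LEVELS)
}

#' Genomic region distribution of clusters
#'
#' @param clusters Stranded `GRanges` (non-empty).
#' @param transcripts A `TranscriptModels` list.
#' @return A named numeric vector of fractions over the five region
#'   labels (summing to 1) with an additional `exonic` aggregate
#'   (5' UTR + CDS + 3' UTR).
#' @export
region_distribution <- function(clusters, transcripts) {
  if (length(clusters) == 0L)
    stop("region_distribution requires at least one cluster",
         call. = FALSE)
  labels <- assign_region(clusters, transcripts)
  frac <- as.numeric(table(labels)) / length(clusters)
  names(frac) <- .REGION_LEVELS
  c(frac, exonic = sum(frac[c("five_prime_utr", "cds",
                              "three_prime_utr")]))
}

#' Fraction of one cluster set overlapping another
#'
#' A cluster of `clusters_a` counts as shared iff it overlaps >= 1 nt of
#' any same-strand cluster of `clusters_b`. The fraction is
#' `|shared| / |A|` and is asymmetric by design.
#'
#' @param clusters_a,clusters_b Stranded `GRanges`.
#' @return A single fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(clusters_a, clusters_b) {
  if (length(clusters_a) == 0L)
    stop("overlap_fraction requires a non-empty first set",
         call. = FALSE)
  .check_stranded(clusters_a, "cluster")
  .check_stranded(clusters_b, "cluster")
  mean(countOverlaps(clusters_a, clusters_b, minoverlap = 1L) > 0L)
}

#' Write per-cluster region labels and their summary
#'
#' @param clusters Stranded `GRanges` with a `cluster_id` metadata
#'   column.
#' @param transcripts A `TranscriptModels` list.
#' @param label_path,summary_path Output TSV paths.
#' @return Invisibly, the region distribution.
#' @export
write_region_tables <- function(clusters, transcripts, label_path,
                                summary_path) {
  labels <- assign_region(clusters, transcripts)
  write.table(
    data.frame(cluster_id = mcols(clusters)$cluster_id,
               label = as.character(labels)),
    label_path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- table(labels)
  write.table(
    data.frame(label = names(tab), count = as.integer(tab),
               fraction = as.numeric(tab) / length(clusters)),
    summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(region_distribution(clusters, transcripts))
}
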