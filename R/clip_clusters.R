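# PCR-duplicate collapsing, strand-aware cluster calling across
# replicates, and biological-complexity / peak-height annotation.

#' Collapse PCR duplicates to unique tags
#'
#' Within each replicate, tags with identical (chrom, start, end, strand)
#' collapse to a single unique tag. The output is sorted by coordinate
#' (then strand, then replicate) so it is independent of input order.
#'
#' @param tags Stranded `GRanges` with metadata column `replicate`.
#' @return The unique tags, coordinate-sorted.
#' @export
collapse_duplicates <- function(tags) {
  .check_stranded(tags, "tag")
  if (is.null(mcols(tags)$replicate))
    stop("tags must carry a 'replicate' metadata column", call. = FALSE)
  key <- paste(as.character(seqnames(tags)), start(tags), end(tags),
               as.character(strand(tags)), mcols(tags)$replicate,
               sep = "\r")
  uniq <- tags[!duplicated(key)]
  ord <- order(as.integer(match(seqnames(uniq), seqlevels(uniq))),
               start(uniq), end(uniq),
               as.integer(strand(uniq)), mcols(uniq)$replicate)
  uniq[ord]
}

#' Per-replicate unique-tag counts
#'
#' @param tags Unique tags from [collapse_duplicates()].
#' @return An integer vector of counts named by replicate.
#' @export
unique_tag_counts <- function(tags) {
  reps <- mcols(tags)$replicate
  tab <- table(reps)
  setNames(as.integer(tab), names(tab))
}

#' Tally per-replicate unique-tag counts
#'
#' @param counts Numeric vector of per-replicate unique-tag counts
#'   (at least one replicate).
#' @return A list with `per_replicate` and `total`.
#' @export
tally_tags <- function(counts) {
  if (length(counts) < 1L)
    stop("at least one replicate is required", call. = FALSE)
  list(per_replicate = counts, total = sum(counts))
}

#' Call strand-aware CLIP clusters
#'
#' Clusters are the connected components of unique tags under >= 1 nt
#' same-strand overlap (abutting tags do not join). Each cluster spans
#' exactly the union of its member tags and is annotated with
#' per-replicate tag counts, biological complexity (`bc`, the number of
#' replicates contributing >= 1 tag) and peak height (`ph`, the maximum
#' per-base tag depth within the cluster).
#'
#' @param tags Unique tags from [collapse_duplicates()].
#' @param n_replicates Total number of replicates (columns of the count
#'   matrix); defaults to the largest replicate id present.
#' @return A `GRanges` of clusters, coordinate-sorted, with metadata
#'   columns `cluster_id`, `rep_counts` (matrix), `total_tags`, `bc`,
#'   `ph`.
#' @export
call_clusters <- function(tags, n_replicates = NULL) {
  .check_stranded(tags, "tag")
  reps <- mcols(tags)$replicate
  if (is.null(n_replicates))
    n_replicates <- if (length(tags)) max(as.integer(reps)) else 0L
  clusters <- reduce(granges(tags), min.gapwidth = 0L)
  if (length(clusters) == 0L) {
    mcols(clusters) <- DataFrame(
      cluster_id = character(0),
      rep_counts = I(matrix(0L, 0L, n_replicates)),
      total_tags = integer(0), bc = integer(0), ph = integer(0))
    return(clusters)
  }
  hits <- findOverlaps(tags, clusters)
  tab <- table(
    factor(subjectHits(hits), levels = seq_along(clusters)),
    factor(as.integer(reps)[queryHits(hits)],
           levels = seq_len(n_replicates)))
  counts <- matrix(as.integer(tab), nrow = length(clusters))

  ph <- integer(length(clusters))
  for (s in c("+", "-")) {
    on_s <- as.logical(strand(clusters) == s)
    if (!any(on_s)) next
    cov <- coverage(tags[strand(tags) == s])
    cl_s <- clusters[on_s]
    idx_s <- which(on_s)
    for (chr in unique(as.character(seqnames(cl_s)))) {
      sel <- as.character(seqnames(cl_s)) == chr
      v <- Views(cov[[chr]], ranges(cl_s)[sel])
      ph[idx_s[sel]] <- as.integer(viewMaxs(v))
    }
  }

  mcols(clusters) <- DataFrame(
    cluster_id = sprintf("cl%05d", seq_along(clusters)),
    rep_counts = I(counts),
    total_tags = as.integer(rowSums(counts)),
    bc = as.integer(rowSums(counts > 0L)),
    ph = ph)
  clusters
}

#' Filter clusters by biological complexity and peak height
#'
#' Keeps exactly the clusters with `bc >= min_bc` and `ph >= min_ph`. The
#' fraction passing, as a percentage rounded to the nearest integer, is
#' attached as attribute `pass_percent`.
#'
#' @param clusters Output of [call_clusters()].
#' @param min_bc Minimum biological complexity (default 2, i.e. BC2).
#' @param min_ph Minimum peak height (default 1; use 10 for the robust
#'   PH >= 10 set).
#' @param n_replicates If supplied, `min_bc > n_replicates` is rejected
#'   as a configuration error.
#' @return The passing subset, with attribute `pass_percent`.
#' @export
filter_clusters <- function(clusters, min_bc = 2L, min_ph = 1L,
                            n_replicates = NULL) {
  if (!is.null(n_replicates) && min_bc > n_replicates)
    stop("min_bc exceeds the number of replicates", call. = FALSE)
  keep <- mcols(clusters)$bc >= min_bc & mcols(clusters)$ph >= min_ph
  out <- clusters[keep]
  attr(out, "pass_percent") <- pass_percent(sum(keep), length(clusters))
  out
}

#' Percentage of clusters passing a filter
#'
#' @param n_pass,n_total Cluster counts.
#' @return `100 * n_pass / n_total`, rounded to the nearest integer
#'   (half away from zero).
#' @export
pass_percent <- function(n_pass, n_total) {
  if (n_total == 0L) return(NA_integer_)
  as.integer(floor(100 * n_pass / n_total + 0.5))
}

#' Write a cluster table (BED6 plus TSV sidecar)
#'
#' The BED score column carries the peak height; the sidecar TSV carries
#' cluster id, per-replicate counts, bc, ph and total tags.
#'
#' @param clusters Output of [call_clusters()].
#' @param bed_path,tsv_path Output paths.
#' @return Invisibly, `bed_path`.
#' @export
write_cluster_table <- function(clusters, bed_path, tsv_path) {
  gr <- granges(clusters)
  mcols(gr)$name <- mcols(clusters)$cluster_id
  mcols(gr)$score <- mcols(clusters)$ph
  write_tag_table(gr, bed_path)
  counts <- unclass(mcols(clusters)$rep_counts)
  df <- data.frame(cluster_id = mcols(clusters)$cluster_id,
                   counts,
                   bc = mcols(clusters)$bc, ph = mcols(clusters)$ph,
                   total_tags = mcols(clusters)$total_tags)
  names(df)[seq_len(ncol(counts)) + 1L] <-
    paste0("rep", seq_len(ncol(counts)))
  write.table(df, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(bed_path)
}
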