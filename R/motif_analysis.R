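# Tetramer enrichment in cluster sequences versus shuffled controls,
# YCAY matching, and positional YCAY enrichment around cluster anchors.
# All sequences are RNA (A,C,G,U,N); N never matches any motif.

#' Find YCAY motif matches in an RNA sequence
#'
#' Reports the 1-based start position of every window matching Y-C-A-Y
#' (Y in `{C,U}`); overlapping matches are all reported and N matches
#' nothing.
#'
#' @param rna A single RNA sequence (character, alphabet `{A,C,G,U,N}`).
#' @return An integer vector of match start positions (empty when the
#'   sequence is shorter than 4 nt or has no match).
#' @export
ycay_scan <- function(rna) {
  if (nchar(rna) < 4L) return(integer(0))
  m <- gregexpr("(?=[CU]CA[CU])", rna, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m)
}

#' Count all 256 tetramers over a set of RNA sequences
#'
#' Overlapping 4-nt windows are counted, pooled across sequences; windows
#' containing N are skipped.
#'
#' @param sequences Character vector of RNA sequences.
#' @return A named integer vector over all 256 ACGU tetramers.
#' @export
count_tetramers <- function(sequences) {
  set <- RNAStringSet(as.character(sequences))
  freq <- oligonucleotideFrequency(set, width = 4L)
  counts <- if (nrow(freq)) colSums(freq) else
    setNames(numeric(ncol(freq)), colnames(freq))
  storage.mode(counts) <- "integer"
  counts
}

#' Generate composition-preserving shuffled control sequence sets
#'
#' Each control sequence is an independent within-sequence mononucleotide
#' permutation: length and base composition are preserved exactly.
#'
#' @param sequences Character vector of RNA sequences.
#' @param n_shuffles Number of control sets (>= 1).
#' @param seed Integer seed; output is deterministic under a fixed seed.
#' @return A list of `n_shuffles` character vectors, each parallel to
#'   `sequences`.
#' @export
shuffle_controls <- function(sequences, n_shuffles = 100L, seed = 1L) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1", call. = FALSE)
  set.seed(seed)
  letters_list <- strsplit(as.character(sequences), "")
  lapply(seq_len(n_shuffles), function(i) {
    vapply(letters_list, function(x) {
      paste(sample(x, length(x)), collapse = "")
    }, character(1L))
  })
}

#' Rank tetramer enrichment against shuffled controls
#'
#' Enrichment is `(observed + 1) / (mean shuffled count + 1)`; the
#' pseudocount keeps ratios finite for absent tetramers. Rows are sorted
#' by decreasing enrichment, ties broken lexicographically by kmer.
#'
#' @param observed Named counts from [count_tetramers()] on the observed
#'   sequences.
#' @param control_counts A list of named count vectors, one per shuffled
#'   control set, over the same kmer universe.
#' @return A data frame with columns `kmer`, `observed`, `shuffled_mean`,
#'   `shuffled_sd`, `enrichment`, sorted by rank.
#' @export
rank_enrichment <- function(observed, control_counts) {
  if (length(control_counts) == 0L)
    stop("at least one shuffled control set is required", call. = FALSE)
  kmers <- names(observed)
  ctrl <- vapply(control_counts, function(x) as.numeric(x[kmers]),
                 numeric(length(kmers)))
  ctrl <- matrix(ctrl, nrow = length(kmers))
  mu <- rowMeans(ctrl)
  sdv <- if (ncol(ctrl) > 1L) apply(ctrl, 1L, sd) else
    rep(NA_real_, length(kmers))
  enr <- (as.numeric(observed) + 1) / (mu + 1)
  out <- data.frame(kmer = kmers, observed = as.numeric(observed),
                    shuffled_mean = mu, shuffled_sd = sdv,
                    enrichment = enr, stringsAsFactors = FALSE)
  out[order(-out$enrichment, out$kmer), , drop = FALSE]
}

#' Positional YCAY profile around cluster anchors
#'
#' Anchors each cluster at its midpoint, extracts the strand-matched RNA
#' over `[-flank, +flank]`, and reports the per-offset fraction of
#' windows with a YCAY match starting there, together with the matching
#' background from composition-preserving shuffles of the same windows.
#' Windows extending beyond chromosome bounds are dropped.
#'
#' @param clusters Stranded `GRanges` of clusters.
#' @param genome A named `DNAStringSet`.
#' @param flank Half-width of the window (nt).
#' @param n_shuffles Shuffled control sets for the background.
#' @param seed Seed for the shuffles.
#' @return A data frame with columns `offset` (relative to the anchor),
#'   `frequency`, `background`, `background_sd`, plus attribute
#'   `n_windows`.
#' @export
ycay_positional_profile <- function(clusters, genome, flank = 500L,
                                    n_shuffles = 20L, seed = 1L) {
  if (flank < 0L) stop("flank must be >= 0", call. = FALSE)
  anchors <- cluster_anchor(clusters)
  # pad 3 nt on both sides so a 4-mer starting at +/- flank fits and the
  # anchor stays centred after minus-strand reverse-complementation
  win <- GRanges(seqnames(clusters),
                 IRanges(anchors - flank - 3L, anchors + flank + 3L),
                 strand = strand(clusters))
  lens <- setNames(width(genome), names(genome))
  ok <- start(win) >= 1L &
    end(win) <= lens[as.character(seqnames(win))]
  win <- win[ok]
  if (length(win) == 0L)
    stop("no cluster window lies fully within chromosome bounds",
         call. = FALSE)
  seqs <- fetch_rna(genome, win)
  offsets <- seq(-flank, flank)
  freq <- .ycay_offset_freq(seqs, flank)
  shuffles <- shuffle_controls(seqs, n_shuffles = n_shuffles, seed = seed)
  bg_mat <- vapply(shuffles, .ycay_offset_freq, numeric(2L * flank + 1L),
                   flank = flank)
  bg_mat <- matrix(bg_mat, nrow = 2L * flank + 1L)
  out <- data.frame(offset = offsets, frequency = freq,
                    background = rowMeans(bg_mat),
                    background_sd = if (ncol(bg_mat) > 1L)
                      apply(bg_mat, 1L, sd) else NA_real_)
  attr(out, "n_windows") <- length(win)
  out
}

# Per-offset YCAY start frequency over windows of width 2*flank + 7
# whose anchor sits at sequence position flank + 4; match position p
# corresponds to offset p - (flank + 4).
.ycay_offset_freq <- function(seqs, flank) {
  hits <- numeric(2L * flank + 1L)
  for (s in seqs) {
    off <- ycay_scan(s) - (flank + 4L)
    off <- off[off >= -flank & off <= flank]
    hits[off + flank + 1L] <- hits[off + flank + 1L] + 1
  }
  hits / length(seqs)
}

#' Cluster anchor positions (midpoints)
#'
#' Deterministic midpoint, `(start + end) %/% 2` on 1-based closed
#' coordinates.
#'
#' @param clusters A `GRanges`.
#' @return Integer vector of anchor positions.
#' @export
cluster_anchor <- function(clusters) {
  (start(clusters) + end(clusters)) %/% 2L
}

#' Extract strand-matched RNA sequences of clusters
#'
#' @param clusters Stranded `GRanges`.
#' @param genome A named `DNAStringSet`.
#' @return Character vector of RNA sequences on each cluster's strand.
#' @export
cluster_sequences <- function(clusters, genome) {
  fetch_rna(genome, clusters)
}
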