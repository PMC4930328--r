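# Independent brute-force oracles, deliberately naive implementations
# kept separate from the package's own code paths.

# Two-sided Fisher exact p by direct hypergeometric enumeration over all
# tables with the observed margins.
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  n <- a + b + c + d
  c1 <- a + c
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  lp <- lchoose(r1, xs) + lchoose(n - r1, c1 - xs) - lchoose(n, c1)
  p <- exp(lp)
  p_obs <- exp(lchoose(r1, a) + lchoose(n - r1, c1 - a) -
                 lchoose(n, c1))
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Connected components of stranded intervals under >= 1 nt same-strand
# overlap, via an explicit union-find over the pairwise-overlap graph.
oracle_unionfind_clusters <- function(gr) {
  n <- length(gr)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  chrom <- as.character(GenomicRanges::seqnames(gr))
  str <- as.character(GenomicRanges::strand(gr))
  s <- GenomicRanges::start(gr)
  e <- GenomicRanges::end(gr)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (chrom[i] == chrom[j] && str[i] == str[j] &&
          s[i] <= e[j] && s[j] <= e[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  df <- do.call(rbind, lapply(comps, function(idx) {
    data.frame(chrom = chrom[idx[1]], start = min(s[idx]),
               end = max(e[idx]), strand = str[idx[1]],
               n_tags = length(idx))
  }))
  df[order(df$chrom, df$start, df$strand), , drop = FALSE]
}

# Sliding-window tetramer counts, skipping windows containing N.
oracle_kmer_counts <- function(seqs, k = 4L) {
  alph <- c("A", "C", "G", "U")
  kmers <- apply(expand.grid(rep(list(alph), k))[, k:1], 1, paste,
                 collapse = "")
  counts <- setNames(integer(length(kmers)), sort(kmers))
  for (s in seqs) {
    if (nchar(s) < k) next
    for (i in seq_len(nchar(s) - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      if (grepl("N", w, fixed = TRUE)) next
      counts[w] <- counts[w] + 1L
    }
  }
  counts
}

# All-pairs overlap fraction.
oracle_overlap_fraction <- function(a, b) {
  ca <- as.character(GenomicRanges::seqnames(a))
  cb <- as.character(GenomicRanges::seqnames(b))
  sa <- as.character(GenomicRanges::strand(a))
  sb <- as.character(GenomicRanges::strand(b))
  shared <- vapply(seq_along(a), function(i) {
    any(ca[i] == cb & sa[i] == sb &
          GenomicRanges::start(a)[i] <= GenomicRanges::end(b) &
          GenomicRanges::start(b) <= GenomicRanges::end(a)[i])
  }, logical(1))
  mean(shared)
}

# Per-replicate set-of-keys duplicate removal.
oracle_dedup_keys <- function(gr) {
  key <- paste(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), GenomicRanges::end(gr),
               as.character(GenomicRanges::strand(gr)),
               S4Vectors::mcols(gr)$replicate)
  sort(unique(key))
}

# Random stranded tag set for oracle comparisons.
random_tags <- function(n, seed, n_chrom = 2L, span = 5000L,
                        width_range = c(20L, 40L), n_rep = 3L) {
  set.seed(seed)
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  s <- sample(span, n, replace = TRUE)
  gr <- GenomicRanges::GRanges(
    paste0("chr", sample(n_chrom, n, replace = TRUE)),
    IRanges::IRanges(s, width = w),
    strand = sample(c("+", "-"), n, replace = TRUE))
  S4Vectors::mcols(gr)$replicate <- sample(n_rep, n, replace = TRUE)
  gr
}
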