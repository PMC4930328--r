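# Cassette-exon inclusion quantification from junction counts, Fisher
# exact testing of two-genotype differences, BH FDR control, and
# filtering of precomputed differential-expression tables.
#
# Inclusion ratio from pooled counts: m = (up_inc + down_inc) / 2 (a
# single inclusion is witnessed by two junctions, so averaging avoids
# double-counting), I = m / (m + excl). delta-I = I_KO - I_WT.

#' Inclusion ratio from pooled junction counts
#'
#' @param up_inc,down_inc,excl Non-negative junction read counts pooled
#'   across replicates of one genotype.
#' @return `I = m / (m + excl)` with `m = (up_inc + down_inc) / 2`, or
#'   `NA` when all three counts are zero (undefined; the event should be
#'   flagged and excluded upstream).
#' @export
inclusion_ratio <- function(up_inc, down_inc, excl) {
  m <- (up_inc + down_inc) / 2
  out <- m / (m + excl)
  out[up_inc + down_inc + excl == 0] <- NA_real_
  out
}

#' Fisher exact test of a two-genotype inclusion difference
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `[[m_wt, excl_wt], [m_ko, excl_ko]]`, where `m = (up + down) / 2` is
#' rounded half-up to the nearest integer.
#'
#' @param wt_counts,ko_counts Numeric vectors `c(up_inc, down_inc, excl)`
#'   of pooled counts for each genotype.
#' @return The two-sided p-value in `(0, 1]`.
#' @export
event_test <- function(wt_counts, ko_counts) {
  m_wt <- floor((wt_counts[1L] + wt_counts[2L]) / 2 + 0.5)
  m_ko <- floor((ko_counts[1L] + ko_counts[2L]) / 2 + 0.5)
  tab <- matrix(c(m_wt, wt_counts[3L], m_ko, ko_counts[3L]),
                nrow = 2L, byrow = TRUE)
  fisher.test(tab, alternative = "two.sided")$p.value
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_(j>=i)(p_(j) * n / j)`, capped at 1
#' and mapped back to input order.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return q-values in input order (empty input gives empty output).
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  p.adjust(p_values, method = "BH")
}

#' Per-event splicing results across two genotypes
#'
#' Pools junction counts across replicates within each genotype,
#' excludes events whose pooled total falls below `min_total_reads` in
#' either genotype (the low-expression filter), and computes inclusion
#' ratios, delta-I (`I_KO - I_WT`), Fisher p-values and BH FDR over the
#' tested events.
#'
#' @param events Data frame with at least `event_id` (and optionally
#'   `gene_id`); every event must have counts.
#' @param counts Junction-count data frame with columns `event_id`,
#'   `genotype` (`WT`/`KO`), `replicate`, `up_inc`, `down_inc`, `excl`.
#' @param min_total_reads Minimum pooled junction reads per genotype
#'   (default 20).
#' @return A data frame with one row per event: `event_id`, `gene_id`
#'   (if supplied), `i_wt`, `i_ko`, `delta_i`, `p_value`, `fdr`,
#'   `total_reads`, `tested`. Filtered events carry `NA` p-value and
#'   FDR.
#' @export
splicing_table <- function(events, counts, min_total_reads = 20L) {
  need <- c("event_id", "genotype", "replicate", "up_inc", "down_inc",
            "excl")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("counts table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  ids <- events$event_id
  missing_ev <- setdiff(ids, counts$event_id)
  if (length(missing_ev))
    stop("no junction counts for event ", missing_ev[1L], call. = FALSE)

  pool <- function(geno) {
    sub <- counts[counts$genotype == geno, , drop = FALSE]
    agg <- rowsum(sub[, c("up_inc", "down_inc", "excl")],
                  group = sub$event_id)
    agg[match(ids, rownames(agg)), , drop = FALSE]
  }
  wt <- pool("WT")
  ko <- pool("KO")
  tot_wt <- rowSums(wt)
  tot_ko <- rowSums(ko)
  tested <- !is.na(tot_wt) & !is.na(tot_ko) &
    tot_wt >= min_total_reads & tot_ko >= min_total_reads

  res <- data.frame(event_id = ids, stringsAsFactors = FALSE)
  if (!is.null(events$gene_id)) res$gene_id <- events$gene_id
  res$i_wt <- inclusion_ratio(wt$up_inc, wt$down_inc, wt$excl)
  res$i_ko <- inclusion_ratio(ko$up_inc, ko$down_inc, ko$excl)
  res$delta_i <- res$i_ko - res$i_wt
  res$p_value <- NA_real_
  for (i in which(tested))
    res$p_value[i] <- event_test(as.numeric(wt[i, ]),
                                 as.numeric(ko[i, ]))
  res$fdr <- NA_real_
  res$fdr[tested] <- bh_fdr(res$p_value[tested])
  res$total_reads <- tot_wt + tot_ko
  res$tested <- tested
  res
}

#' Filter a precomputed differential-expression table
#'
#' Keeps transcripts with `FDR < max_fdr` and `|log2FC| >= min_abs_log2fc`
#' (the defaults reproduce the conventional FDR < 0.05, |log2FC| >= 1
#' rule).
#'
#' @param de_table Data frame with columns `transcript`, `log2FC`,
#'   `FDR`.
#' @param max_fdr,min_abs_log2fc Thresholds.
#' @return The passing subset of rows, with attribute `n_pass`.
#' @export
de_filter <- function(de_table, max_fdr = 0.05, min_abs_log2fc = 1) {
  need <- c("transcript", "log2FC", "FDR")
  miss <- setdiff(need, names(de_table))
  if (length(miss))
    stop("DE table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  keep <- de_table$FDR < max_fdr &
    abs(de_table$log2FC) >= min_abs_log2fc
  out <- de_table[keep, , drop = FALSE]
  attr(out, "n_pass") <- sum(keep)
  out
}

#' Write a splicing results table as TSV
#' @param results Data frame from [splicing_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_splicing_table <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
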