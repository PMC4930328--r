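# Readers/writers for the standard formats and the coordinate conventions
# the rest of the package relies on. Internal convention: GRanges, 1-based
# closed, strand always '+' or '-'. BED is 0-based half-open and converted
# on read/write; GTF is 1-based closed and used as-is.

.check_stranded <- function(gr, what = "interval") {
  s <- as.character(strand(gr))
  if (any(s == "*"))
    stop(what, "s must carry an explicit '+' or '-' strand", call. = FALSE)
  invisible(gr)
}

#' Read a BED6 CLIP tag table
#'
#' Parses a 6-column BED file of aligned CLIP tags into a stranded
#' `GRanges`. Coordinates are converted from BED's 0-based half-open
#' convention to the package's 1-based closed convention. Malformed
#' records are reported with their line number.
#'
#' @param path Path to a BED6 file (whitespace-delimited).
#' @param replicate Replicate identifier attached to every record. When
#'   `NULL`, the BED name column is used as the replicate id.
#' @return A `GRanges` with metadata columns `name` and `replicate`,
#'   in file order.
#' @export
read_tag_table <- function(path, replicate = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    gr <- GRanges()
    mcols(gr)$name <- character(0)
    mcols(gr)$replicate <- if (is.null(replicate)) character(0) else
      vector(mode = class(replicate), length = 0L)
    return(gr)
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  short <- which(lengths(fields) < 6L)
  if (length(short))
    stop("line ", short[1L], ": expected 6 BED columns (missing strand?)",
         call. = FALSE)
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  start0 <- suppressWarnings(as.numeric(m[, 2L]))
  end1 <- suppressWarnings(as.numeric(m[, 3L]))
  bad <- which(!is.finite(start0) | !is.finite(end1))
  if (length(bad))
    stop("line ", bad[1L], ": non-numeric start/end", call. = FALSE)
  bad <- which(end1 <= start0 | start0 < 0)
  if (length(bad))
    stop("line ", bad[1L], ": interval end must be greater than start",
         call. = FALSE)
  bad <- which(!m[, 6L] %in% c("+", "-"))
  if (length(bad))
    stop("line ", bad[1L], ": missing or invalid strand (must be + or -)",
         call. = FALSE)
  gr <- GRanges(m[, 1L], IRanges(start0 + 1, end1), strand = m[, 6L])
  mcols(gr)$name <- m[, 4L]
  mcols(gr)$replicate <- if (is.null(replicate)) m[, 4L] else
    rep(replicate, length(gr))
  gr
}

#' Write a tag or cluster table as BED6
#'
#' @param gr Stranded `GRanges`. An optional `name` metadata column fills
#'   the BED name field; an optional `score` column fills the score field.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tag_table <- function(gr, path) {
  .check_stranded(gr, "tag")
  name <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name)
          else if (!is.null(mcols(gr)$replicate))
            as.character(mcols(gr)$replicate)
          else rep(".", length(gr))
  score <- if (!is.null(mcols(gr)$score)) mcols(gr)$score
           else rep(0L, length(gr))
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = name, score = score,
                   strand = as.character(strand(gr)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Imports `exon` (and optional `CDS`) features grouped by
#' `transcript_id` and returns one transcript model per transcript.
#' Exons are stored 5' to 3' in transcript orientation; introns are the
#' gaps between consecutive exons. CDS bounds are the genomic extremes of
#' the CDS features when present, `NA` otherwise.
#'
#' @param path Path to a GTF file.
#' @return A list of transcript models (class `TranscriptModels`), each a
#'   list with elements `transcript_id`, `gene_id`, `strand`, `exons`
#'   (`GRanges`), `cds_start`, `cds_end`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L)
    return(structure(list(), class = "TranscriptModels"))
  if (any(is.na(ex$transcript_id)))
    stop("exon feature without transcript_id", call. = FALSE)
  cds <- gr[gr$type == "CDS"]
  models <- lapply(split(seq_along(ex), ex$transcript_id), function(i) {
    exons <- granges(ex[i])
    if (!isDisjoint(exons))
      stop("overlapping exons within transcript ",
           ex$transcript_id[i[1L]], call. = FALSE)
    strand_chr <- as.character(strand(exons))[1L]
    exons <- exons[order(start(exons), decreasing = (strand_chr == "-"))]
    tid <- ex$transcript_id[i[1L]]
    ci <- which(!is.na(cds$transcript_id) & cds$transcript_id == tid)
    transcript_model(
      transcript_id = tid,
      gene_id = if (is.null(ex$gene_id)) NA_character_ else
        ex$gene_id[i[1L]],
      strand = strand_chr,
      exons = exons,
      cds_start = if (length(ci)) min(start(cds[ci])) else NA_integer_,
      cds_end = if (length(ci)) max(end(cds[ci])) else NA_integer_)
  })
  structure(unname(models)[order(vapply(models, `[[`, "",
                                        "transcript_id"))],
            class = "TranscriptModels")
}

#' Construct a transcript model
#'
#' @param transcript_id,gene_id Identifiers.
#' @param strand `"+"` or `"-"`.
#' @param exons `GRanges` of exons, 5' to 3' in transcript orientation,
#'   non-overlapping.
#' @param cds_start,cds_end Optional genomic CDS bounds (1-based, closed).
#' @return A list of class `TranscriptModel`.
#' @export
transcript_model <- function(transcript_id, gene_id, strand, exons,
                             cds_start = NA_integer_,
                             cds_end = NA_integer_) {
  stopifnot(strand %in% c("+", "-"))
  if (!isDisjoint(exons))
    stop("overlapping exons within transcript ", transcript_id,
         call. = FALSE)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 strand = strand, exons = exons,
                 cds_start = cds_start, cds_end = cds_end),
            class = "TranscriptModel")
}

#' Introns of a transcript model
#'
#' Gaps between consecutive exons, returned 5' to 3' in transcript
#' orientation.
#'
#' @param model A `TranscriptModel`.
#' @return A `GRanges` of introns (possibly empty).
#' @export
transcript_introns <- function(model) {
  ex <- model$exons
  if (length(ex) < 2L) {
    out <- GRanges()
    return(out)
  }
  ex_sorted <- ex[order(start(ex))]
  s <- end(ex_sorted)[-length(ex_sorted)] + 1L
  e <- start(ex_sorted)[-1L] - 1L
  introns <- GRanges(seqnames(ex)[1L], IRanges(s, e),
                     strand = model$strand)
  if (model$strand == "-") introns <- rev(introns)
  introns
}

#' Write transcript models as GTF
#'
#' @param models A `TranscriptModels` list.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(models, path) {
  rows <- lapply(models, function(m) {
    ex <- m$exons[order(start(m$exons))]
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                        m$gene_id, m$transcript_id)
    ex_rows <- data.frame(
      seqname = as.character(seqnames(ex)), source = "clipmap",
      feature = "exon", start = start(ex), end = end(ex), score = ".",
      strand = m$strand, frame = ".", attributes = attr_str)
    if (!is.na(m$cds_start)) {
      cds <- restrict(ex, start = as.integer(m$cds_start),
                      end = as.integer(m$cds_end))
      cds <- cds[width(cds) > 0L]
      cds_rows <- data.frame(
        seqname = as.character(seqnames(cds)), source = "clipmap",
        feature = "CDS", start = start(cds), end = end(cds), score = ".",
        strand = m$strand, frame = "0", attributes = attr_str)
      ex_rows <- rbind(ex_rows, cds_rows)
    }
    ex_rows
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome from FASTA
#'
#' @param path Path to an uncompressed FASTA file.
#' @return A named `DNAStringSet`.
#' @export
read_genome <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome as FASTA
#'
#' @param genome A named `DNAStringSet`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genome <- function(genome, path) {
  writeXStringSet(genome, path)
  invisible(path)
}

#' Fetch transcribed RNA sequence for stranded intervals
#'
#' Extracts the genomic sequence under each interval and returns the RNA
#' on the interval's strand: plus-strand intervals give the reference
#' sequence with T replaced by U; minus-strand intervals give the reverse
#' complement, then T replaced by U.
#'
#' @param genome A named `DNAStringSet`.
#' @param intervals Stranded `GRanges`.
#' @return A character vector of RNA sequences over `{A,C,G,U,N}`, one
#'   per interval.
#' @export
fetch_rna <- function(genome, intervals) {
  .check_stranded(intervals)
  chroms <- as.character(seqnames(intervals))
  missing_chr <- setdiff(unique(chroms), names(genome))
  if (length(missing_chr))
    stop("chromosome not in genome: ", missing_chr[1L], call. = FALSE)
  lens <- setNames(width(genome), names(genome))
  if (any(start(intervals) < 1L | end(intervals) > lens[chroms]))
    stop("interval out of chromosome bounds", call. = FALSE)
  strands <- as.character(strand(intervals))
  vapply(seq_along(intervals), function(i) {
    x <- subseq(genome[[chroms[i]]], start(intervals)[i],
                end(intervals)[i])
    if (strands[i] == "-") x <- reverseComplement(x)
    chartr("T", "U", as.character(x))
  }, character(1L))
}
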