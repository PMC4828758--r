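#' Read a Phred+33 FASTQ file
#'
#' Strict 4-line-record reader. Each record is validated: the header must
#' start with `@`, the separator with `+`, and the quality string must match
#' the sequence length; violations raise a parse error naming the record
#' index. Sequences are uppercased; the alphabet is checked against
#' A/C/G/T/U/N.
#'
#' @param path FASTQ file path, or a character vector of FASTQ lines.
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else path
  if (length(lines) == 0L)
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  if (length(lines) %% 4L != 0L)
    stop(sprintf("truncated FASTQ: %d lines is not a multiple of 4",
                 length(lines)), call. = FALSE)
  n <- length(lines) %/% 4L
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  ql <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hd, "@"))
  if (length(bad))
    stop(sprintf("FASTQ record %d: header does not start with '@'", bad[1]),
         call. = FALSE)
  bad <- which(!startsWith(pl, "+"))
  if (length(bad))
    stop(sprintf("FASTQ record %d: separator does not start with '+'",
                 bad[1]), call. = FALSE)
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad))
    stop(sprintf(
      "FASTQ record %d: quality length %d does not match sequence length %d",
      bad[1], nchar(ql[bad[1]]), nchar(sq[bad[1]])), call. = FALSE)
  bad <- which(grepl("[^ACGTUN]", sq))
  if (length(bad))
    stop(sprintf("FASTQ record %d: sequence contains non-ACGTUN characters",
                 bad[1]), call. = FALSE)
  data.frame(id = sub("^@", "", sub("\\s.*$", "", hd)), sequence = sq,
             quality = ql, stringsAsFactors = FALSE)
}

#' Quality filter
#'
#' Keeps reads whose mean Phred score is at least `min_mean_phred` and which
#' contain at most `max_n` ambiguous (N) bases.
#'
#' @param reads data.frame from [read_fastq()].
#' @param min_mean_phred mean-quality threshold.
#' @param max_n maximum allowed N bases.
#' @return the data.frame with a logical attribute-free subset of retained
#'   reads; dropped count is available by comparing row counts.
#' @export
quality_filter <- function(reads, min_mean_phred = 20, max_n = 0L) {
  if (nrow(reads) == 0L) return(reads)
  mean_q <- vapply(reads$quality,
                   function(q) mean(phred_scores(q)), numeric(1),
                   USE.NAMES = FALSE)
  n_amb <- nchar(reads$sequence) -
    nchar(gsub("N", "", reads$sequence, fixed = TRUE))
  reads[mean_q >= min_mean_phred & n_amb <= max_n, , drop = FALSE]
}

# leftmost position (1-based) at which a >= min_overlap prefix of the
# adapter matches exactly; the match must be the full adapter or run to the
# read end. 0 = no match.
adapter_hit_pos <- function(seq, adapter, min_overlap) {
  L <- nchar(seq); A <- nchar(adapter)
  if (L < min_overlap) return(0L)
  for (pos in seq_len(L - min_overlap + 1L)) {
    k <- min(A, L - pos + 1L)
    if (substr(seq, pos, pos + k - 1L) == substr(adapter, 1L, k)) return(pos)
  }
  0L
}

#' Trim the 3' adapter
#'
#' Locates the leftmost exact match of the adapter prefix (at least
#' `min_overlap` nt; the full adapter where present) in each read and keeps
#' the 5' insert. Reads without an adapter match are returned untrimmed and
#' flagged; reads whose insert would be empty are dropped.
#'
#' @param reads data.frame with a `sequence` column (and optionally
#'   `quality`, trimmed alongside).
#' @param adapter3 adapter sequence (DNA or RNA space).
#' @param min_overlap minimum adapter prefix length to call a match.
#' @return the data.frame with trimmed `sequence`/`quality` and a logical
#'   `adapter_found` column; empty-insert reads removed.
#' @export
trim_adapter <- function(reads, adapter3, min_overlap = 6L) {
  check_that(nchar(adapter3) > 0, "adapter must be non-empty")
  adapter <- as_dna(adapter3)
  if (nrow(reads) == 0L) {
    reads$adapter_found <- logical(0)
    return(reads)
  }
  seqs <- as_dna(reads$sequence)
  pos <- vapply(seqs, adapter_hit_pos, integer(1), adapter = adapter,
                min_overlap = as.integer(min_overlap), USE.NAMES = FALSE)
  found <- pos > 0L
  keep <- !(found & pos == 1L)  # adapter at position 1 => empty insert
  out <- reads[keep, , drop = FALSE]
  pos <- pos[keep]; found <- found[keep]
  trim_to <- ifelse(found, pos - 1L, nchar(out$sequence))
  out$sequence <- substr(out$sequence, 1L, trim_to)
  if (!is.null(out$quality)) out$quality <- substr(out$quality, 1L, trim_to)
  out$adapter_found <- found
  out
}

#' Length filter
#'
#' Keeps reads with `min_len <= length <= max_len` (both ends inclusive:
#' an 18-nt and a 30-nt read are kept, 17 and 31 are dropped).
#'
#' @param reads data.frame with a `sequence` column.
#' @param min_len,max_len inclusive bounds (nt).
#' @return retained subset.
#' @export
length_filter <- function(reads, min_len = 18L, max_len = 30L) {
  if (min_len > max_len) stop("min_len exceeds max_len", call. = FALSE)
  L <- nchar(reads$sequence)
  reads[L >= min_len & L <= max_len, , drop = FALSE]
}

#' Collapse reads into unique tags
#'
#' One tag per distinct sequence after T->U normalization; `count` is the
#' multiplicity. Tags are ordered by descending count, ties broken by
#' lexicographic sequence, and assigned ids `tag1`, `tag2`, ... in that
#' order, so the result is invariant to input order.
#'
#' @param reads data.frame with a `sequence` column, or a character vector.
#' @return data.frame with `tag_id`, `sequence` (RNA space), `count`.
#' @export
collapse <- function(reads) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  seqs <- as_rna(seqs)
  if (length(seqs) == 0L)
    return(data.frame(tag_id = character(0), sequence = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  tab <- table(seqs)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  out$tag_id <- sprintf("tag%d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("tag_id", "sequence", "count")]
}

#' Run the full preprocessing pipeline on a FASTQ
#'
#' quality filter -> adapter trim -> length filter -> collapse, with a stage
#' count summary mirroring a read-statistics table.
#'
#' @param fastq path to a FASTQ file or a character vector of FASTQ lines.
#' @param adapter3 3' adapter sequence.
#' @param min_mean_phred,max_n quality-filter parameters.
#' @param min_overlap adapter-match minimum overlap.
#' @param min_len,max_len inclusive length bounds.
#' @return list: `tags` (collapsed unique tags), `reads` (the retained,
#'   trimmed reads), `stats` (raw_reads, post_quality, post_adapter,
#'   post_length, unique_tags).
#' @export
preprocess_fastq <- function(fastq, adapter3,
                             min_mean_phred = 20, max_n = 0L,
                             min_overlap = 6L,
                             min_len = 18L, max_len = 30L) {
  raw <- read_fastq(fastq)
  q <- quality_filter(raw, min_mean_phred, max_n)
  t <- trim_adapter(q, adapter3, min_overlap)
  l <- length_filter(t, min_len, max_len)
  tags <- collapse(l)
  stats <- data.frame(stage = c("raw_reads", "post_quality", "post_adapter",
                                "post_length", "unique_tags"),
                      count = c(nrow(raw), nrow(q), nrow(t), nrow(l),
                                nrow(tags)))
  list(tags = tags, reads = l, stats = stats)
}

#' Write collapsed tags as FASTA
#'
#' Uses the collapsed-read header dialect `>tagN_xCOUNT`.
#'
#' @param tags data.frame from [collapse()].
#' @param path output FASTA path.
#' @export
write_collapsed_fasta <- function(tags, path) {
  lines <- as.vector(rbind(sprintf(">%s_x%d", tags$tag_id, tags$count),
                           tags$sequence))
  writeLines(lines, path)
  invisible(lines)
}
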