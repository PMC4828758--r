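#' @useDynLib srnakit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @param space `"rna"` (default: sequences returned U-normalized) or
#'   `"dna"`.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, space = c("rna", "dna")) {
  space <- match.arg(space)
  x <- as.character(Biostrings::readBStringSet(path))
  names(x) <- sub("\\s.*$", "", names(x))
  if (space == "rna") as_rna(x) else as_dna(x)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (DNA or RNA space).
#' @param path output file.
#' @param space written alphabet: `"dna"` or `"rna"`.
#' @export
write_fasta <- function(seqs, path, space = c("dna", "rna")) {
  space <- match.arg(space)
  x <- if (space == "dna") Biostrings::DNAStringSet(as_dna(seqs))
       else Biostrings::RNAStringSet(as_rna(seqs))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Convert sequences to RNA space
#'
#' Uppercases and replaces T with U. All internal sequence handling in srnakit
#' is RNA-space; FASTQ/FASTA input in DNA space is normalized on read.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector in RNA space.
#' @export
as_rna <- function(x) chartr("Tt", "UU", toupper(x))

#' Convert sequences to DNA space
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector in DNA space (U replaced by T).
#' @export
as_dna <- function(x) chartr("Uu", "TT", toupper(x))

#' Reverse a character string
#' @noRd
str_rev <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Reverse complement in RNA space
#'
#' @param x character vector of RNA sequences.
#' @return reverse complements, RNA space.
#' @export
revcomp_rna <- function(x) str_rev(chartr("ACGU", "UGCA", as_rna(x)))

#' Reverse complement in DNA space
#' @param x character vector of DNA sequences.
#' @return reverse complements, DNA space.
#' @export
revcomp_dna <- function(x) str_rev(chartr("ACGT", "TGCA", as_dna(x)))

#' Random RNA sequence(s)
#' @noRd
random_rna <- function(n_seq, len, alphabet = c("A", "C", "G", "U")) {
  len <- rep_len(len, n_seq)
  vapply(seq_len(n_seq), function(i) {
    paste(sample(alphabet, len[i], replace = TRUE), collapse = "")
  }, character(1))
}

#' Split a sequence into single characters
#' @noRd
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Decode a Phred+33 quality string to integer scores
#'
#' @param qual quality string (Phred+33 encoding).
#' @return integer vector of Phred scores.
#' @export
phred_scores <- function(qual) utf8ToInt(qual) - 33L

#' Encode integer Phred scores as a Phred+33 string
#' @param scores integer vector of Phred scores.
#' @return quality string.
#' @export
phred_encode <- function(scores) intToUtf8(as.integer(scores) + 33L)

#' Hamming distance between two equal-length sequences
#' @noRd
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming distance requires equal lengths")
  sum(seq_chars(a) != seq_chars(b))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: permutes a sequence while preserving its exact
#' dinucleotide composition, by shuffling the edge ordering of the sequence's
#' dinucleotide multigraph and verifying that the last-edge choice keeps an
#' Eulerian path ending at the original terminal base. Used as the negative
#' control for hairpin discovery (shuffled windows must retain local
#' composition, or folding propensity would change trivially).
#'
#' @param x a single RNA/DNA sequence.
#' @return a shuffled sequence with identical dinucleotide counts.
#' @export
shuffle_dinucleotide <- function(x) {
  ch <- seq_chars(x)
  n <- length(ch)
  if (n <= 3) return(x)
  letters_used <- unique(ch)
  last <- ch[n]
  # successor lists per source letter
  succ <- split(ch[2:n], ch[1:(n - 1)])
  repeat {
    succ_perm <- lapply(succ, sample)
    # connectivity check: from each letter (except last), the chosen final
    # edge must lie on a path to the terminal letter (Altschul-Erickson).
    ok <- TRUE
    finals <- vapply(succ_perm, function(v) v[length(v)], character(1))
    # walk from each source's final edge toward `last`
    for (s in names(finals)) {
      if (s == last) next
      seen <- character(0)
      cur <- s
      while (!(cur %in% seen) && cur != last && cur %in% names(finals)) {
        seen <- c(seen, cur)
        cur <- finals[[cur]]
      }
      if (cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  # rebuild by walking the shuffled successor lists
  idx <- stats::setNames(rep(1L, length(succ_perm)), names(succ_perm))
  out <- character(n)
  out[1] <- ch[1]
  cur <- ch[1]
  for (i in 2:n) {
    nxt <- succ_perm[[cur]][idx[[cur]]]
    idx[[cur]] <- idx[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Stop unless condition holds
#' @noRd
check_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
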