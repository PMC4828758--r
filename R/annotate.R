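#' Map a tag to the genome (ungapped, mismatch-tolerant)
#'
#' Finds every ungapped alignment of the tag on both genome strands with at
#' most `max_mm` substitutions (exhaustive offset scan, compiled).
#' Coordinates are 0-based half-open on the forward strand; minus-strand
#' hits mean the tag matches the reverse complement at that locus. Mismatch
#' positions are reported 1-based in tag orientation.
#'
#' @param tag tag sequence (RNA or DNA space).
#' @param genome genome as a DNA string.
#' @param max_mm maximum substitutions.
#' @param chrom chromosome name recorded in the result.
#' @return data.frame: `chrom`, `start`, `end`, `strand`, `n_mismatches`,
#'   `mismatch_positions` (comma string); zero rows when there is no hit.
#'   Sorted by (n_mismatches, chrom, start, strand).
#' @export
map_to_genome <- function(tag, genome, max_mm = 1L, chrom = "chr1") {
  check_that(nchar(tag) <= nchar(genome), "tag longer than genome")
  h <- genome_scan_cpp(as_dna(tag), as_dna(genome), as.integer(max_mm))
  out <- data.frame(chrom = rep(chrom, length(h$start)), start = h$start,
                    end = h$start + nchar(tag), strand = h$strand,
                    n_mismatches = h$n_mismatches,
                    mismatch_positions = h$mismatch_positions,
                    stringsAsFactors = FALSE)
  out <- out[order(out$n_mismatches, out$chrom, out$start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match a tag against a reference set by mismatch-tolerant containment
#'
#' A hit exists when the tag aligns ungapped within a reference sequence with
#' at most `max_mm` substitutions at some offset. The best hit has the fewest
#' mismatches; ties are broken by reference order, then smallest offset.
#'
#' @param tag tag sequence (RNA space).
#' @param refs named character vector of reference sequences (RNA space).
#' @param max_mm maximum substitutions.
#' @return list(`reference_id`, `n_mismatches`, `offset` 0-based) or `NULL`.
#' @export
match_reference_set <- function(tag, refs, max_mm = 1L) {
  check_that(length(refs) > 0, "reference set is empty")
  h <- ref_scan_cpp(as_rna(tag), unname(as_rna(refs)), as.integer(max_mm))
  if (h[1] == 0L) return(NULL)
  list(reference_id = names(refs)[h[1]], n_mismatches = h[2],
       offset = h[3])
}

#' Match a tag against known mature miRNAs with end-offset tolerance
#'
#' Aligns the tag to each mature reference allowing 5' and 3' end offsets of
#' up to `max_end_offset` nt each (admitting terminal isomiRs) and at most
#' `max_mm` substitutions within the overlap. The overlap must cover the
#' reference seed (positions 2-8). Best hit by (mismatches, |5' offset|,
#' reference order).
#'
#' @param tag tag sequence (RNA space).
#' @param mature_refs named RNA character vector of mature miRNAs.
#' @param max_mm maximum substitutions in the overlap.
#' @param max_end_offset maximum |offset| allowed at each end.
#' @return list(`reference_id`, `n_mismatches`, `offset5`, `offset3`) or
#'   `NULL`. Offsets are signed nt relative to the reference ends
#'   (negative = tag trimmed relative to the reference).
#' @export
match_conserved_mirna <- function(tag, mature_refs, max_mm = 2L,
                                  max_end_offset = 3L) {
  tag <- as_rna(tag)
  lt <- nchar(tag)
  tc <- seq_chars(tag)
  best <- NULL
  for (ri in seq_along(mature_refs)) {
    ref <- mature_refs[[ri]]
    lr <- nchar(ref)
    rc <- seq_chars(ref)
    for (o5 in seq(-max_end_offset, max_end_offset)) {
      # o5 > 0: tag extends upstream of the reference 5' end
      o3 <- lt - lr - o5
      if (abs(o3) > max_end_offset) next
      # overlap in reference coordinates
      r_from <- max(1L, 1L - o5)
      r_to <- min(lr, lr + min(o3, 0L))
      if (r_from > 2L || r_to < 8L) next  # must cover the seed (ref 2-8)
      t_from <- r_from + o5
      idx <- seq(0L, r_to - r_from)
      nmm <- sum(tc[t_from + idx] != rc[r_from + idx])
      if (nmm > max_mm) next
      cand <- list(reference_id = names(mature_refs)[ri],
                   n_mismatches = nmm, offset5 = o5, offset3 = o3)
      if (is.null(best) ||
          nmm < best$n_mismatches ||
          (nmm == best$n_mismatches && abs(o5) < abs(best$offset5)))
        best <- cand
    }
  }
  best
}

#' Hierarchically classify unique tags
#'
#' Assigns each tag exactly one category with precedence
#' conserved miRNA > rRNA > tRNA > snoRNA > other ncRNA; tags matching no
#' reference but mapping to the genome become `novel_input` (candidate input
#' for hairpin discovery); unmapped tags are `unannotated`. Counts are
#' reported in both total-read and unique-tag units.
#'
#' @param tags collapsed tag data.frame from [collapse()].
#' @param genome genome DNA string.
#' @param ref_sets list with elements `mature` (known mature miRNAs) and any
#'   of `rrna`, `trna`, `snorna`, `other` (RNA character vectors).
#' @param max_mm_genome genome-mapping mismatch tolerance.
#' @param max_mm_ref ncRNA reference-containment mismatch tolerance.
#' @param max_mm_mirna,max_end_offset conserved-miRNA matching tolerances.
#' @return list: `records` (tag_id, category, reference_id, n_mismatches),
#'   `counts` (per-category total reads and unique tags),
#'   `alignments` (genome alignments of novel_input tags, for clustering).
#' @export
classify_tags <- function(tags, genome, ref_sets,
                          max_mm_genome = 1L, max_mm_ref = 1L,
                          max_mm_mirna = 2L, max_end_offset = 3L) {
  ref_names <- unlist(lapply(ref_sets, names), use.names = FALSE)
  if (anyDuplicated(ref_names))
    stop("reference names overlap across sets", call. = FALSE)
  nc_order <- intersect(c("rrna", "trna", "snorna", "other"),
                        names(ref_sets))
  genome_dna <- as_dna(genome)

  n <- nrow(tags)
  category <- character(n)
  reference_id <- character(n)
  n_mismatches <- rep(NA_integer_, n)
  aln_list <- list()

  for (i in seq_len(n)) {
    s <- tags$sequence[i]
    hit <- if (length(ref_sets$mature))
      match_conserved_mirna(s, ref_sets$mature, max_mm_mirna,
                            max_end_offset) else NULL
    if (!is.null(hit)) {
      category[i] <- "conserved_mirna"
      reference_id[i] <- hit$reference_id
      n_mismatches[i] <- hit$n_mismatches
      next
    }
    matched <- FALSE
    for (cl in nc_order) {
      h <- match_reference_set(s, ref_sets[[cl]], max_mm_ref)
      if (!is.null(h)) {
        category[i] <- switch(cl, rrna = "rrna", trna = "trna",
                              snorna = "snorna", other = "other_ncrna")
        reference_id[i] <- h$reference_id
        n_mismatches[i] <- h$n_mismatches
        matched <- TRUE
        break
      }
    }
    if (matched) next
    aln <- map_to_genome(s, genome_dna, max_mm_genome)
    if (nrow(aln)) {
      category[i] <- "novel_input"
      reference_id[i] <- ""
      n_mismatches[i] <- aln$n_mismatches[1]
      aln$tag_id <- tags$tag_id[i]
      aln_list[[length(aln_list) + 1L]] <- aln
    } else {
      category[i] <- "unannotated"
      reference_id[i] <- ""
    }
  }

  records <- data.frame(tag_id = tags$tag_id, category = category,
                        reference_id = reference_id,
                        n_mismatches = n_mismatches,
                        stringsAsFactors = FALSE)
  lvls <- c("conserved_mirna", "rrna", "trna", "snorna", "other_ncrna",
            "novel_input", "unannotated")
  counts <- data.frame(
    category = lvls,
    total_reads = vapply(lvls, function(l)
      sum(tags$count[category == l]), integer(1)),
    unique_tags = vapply(lvls, function(l)
      sum(category == l), integer(1)),
    stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  alignments <- if (length(aln_list)) do.call(rbind, aln_list)
                else data.frame()
  list(records = records, counts = counts, alignments = alignments)
}
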