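#' Percentage with half-up rounding to two decimals
#'
#' `100 * part / whole`, rounded half-up (so 0.125 -> 0.13), the convention
#' that reproduces printed read-statistics tables exactly.
#'
#' @param part,whole counts; `whole` must be positive and `part <= whole`.
#' @return percentage, 2 decimal places.
#' @export
percentage <- function(part, whole) {
  if (any(whole == 0)) stop("percentage: whole is zero", call. = FALSE)
  check_that(all(part <= whole), "percentage: part exceeds whole")
  x <- 100 * part / whole
  floor(x * 100 + 0.5 + 1e-9) / 100
}

#' Category statistics table
#'
#' Formats per-category total-read and unique-tag counts with a percentage
#' column relative to the high-quality read total.
#'
#' @param counts data.frame with `category`, `total_reads`, `unique_tags`.
#' @param high_quality_total denominator for the percentage column.
#' @return the data.frame with a `pct_of_hq` column.
#' @export
category_stats <- function(counts, high_quality_total) {
  counts$pct_of_hq <- percentage(counts$total_reads, high_quality_total)
  counts
}

#' Read-weighted length distribution of tags
#'
#' @param tags collapsed tag data.frame (`sequence`, `count`).
#' @param range length range of the histogram (inclusive).
#' @return list: `histogram` (data.frame `length`, `reads`), `mode` (modal
#'   length; ties broken toward the shorter length).
#' @export
length_distribution <- function(tags, range = c(18L, 30L)) {
  lens <- nchar(tags$sequence)
  bins <- seq(range[1], range[2])
  reads <- vapply(bins, function(l) sum(tags$count[lens == l]), numeric(1))
  hist <- data.frame(length = bins, reads = reads)
  mode <- bins[which.max(reads)]  # which.max takes the first (shorter) tie
  list(histogram = hist, mode = mode)
}

#' Top novel-candidate table
#'
#' One row per named candidate: total supporting read count, number of
#' distinct isomiRs, the most expressed sequence with its length, count and
#' seed — the layout of a most-expressed novel-candidate table.
#'
#' @param candidates named candidate data.frame from [find_novel_mirnas()].
#' @param tags collapsed tag data.frame (sequences and counts).
#' @param n number of candidates reported.
#' @param decreasing sort order on the most-expressed count.
#' @return data.frame: `name`, `total_count`, `n_isomirs`,
#'   `most_expressed_sequence`, `length`, `most_expressed_count`, `seed`.
#' @export
top_novel_table <- function(candidates, tags, n = 10L, decreasing = TRUE) {
  if (nrow(candidates) == 0L)
    return(data.frame(name = character(0), total_count = numeric(0),
                      n_isomirs = integer(0),
                      most_expressed_sequence = character(0),
                      length = integer(0), most_expressed_count = numeric(0),
                      seed = character(0), stringsAsFactors = FALSE))
  counts <- stats::setNames(tags$count, tags$tag_id)
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    sup <- cand$supporting[[1]]
    best <- sup[order(-sup$count, sup$tag_id), ][1, ]
    seqs <- stats::setNames(tags$sequence, tags$tag_id)
    ms <- seqs[[best$tag_id]]
    data.frame(name = cand$name, total_count = cand$total_count,
               n_isomirs = nrow(sup), most_expressed_sequence = ms,
               length = nchar(ms), most_expressed_count = best$count,
               seed = extract_seed(ms), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$most_expressed_count,
                   decreasing = decreasing), , drop = FALSE]
  out <- utils::head(out, n)
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-((target_ct_sample - ref_ct_sample) -
#' (target_ct_calibrator - ref_ct_calibrator))`: the fold change of a target
#' relative to an endogenous control, expressed against a calibrator sample.
#'
#' @param target_ct_sample,ref_ct_sample target and endogenous-control Ct in
#'   the sample of interest.
#' @param target_ct_calibrator,ref_ct_calibrator the same Cts in the
#'   calibrator sample.
#' @return fold change (vectorized).
#' @export
ddct <- function(target_ct_sample, ref_ct_sample,
                 target_ct_calibrator, ref_ct_calibrator) {
  check_that(all(is.finite(c(target_ct_sample, ref_ct_sample,
                             target_ct_calibrator, ref_ct_calibrator))),
             "all Ct values must be finite")
  dct_s <- target_ct_sample - ref_ct_sample
  dct_c <- target_ct_calibrator - ref_ct_calibrator
  2^(-(dct_s - dct_c))
}

#' Per-tissue qPCR fold changes
#'
#' Computes replicate-level 2^-ddCt against the mean delta-Ct of the
#' calibrator tissue and summarizes per (target, tissue) as mean with
#' standard error (or standard deviation).
#'
#' @param qpcr data.frame with columns `target`, `tissue`, `replicate`,
#'   `target_ct`, `ref_ct`.
#' @param calibrator calibrator tissue name.
#' @param spread `"se"` (default) or `"sd"`.
#' @return data.frame: `target`, `tissue`, `fold_change` (mean), `spread`,
#'   `n`.
#' @export
qpcr_fold_changes <- function(qpcr, calibrator = "brain", spread = "se") {
  check_that(spread %in% c("se", "sd"), "spread must be 'se' or 'sd'")
  check_that(calibrator %in% qpcr$tissue, "calibrator tissue absent")
  qpcr$dct <- qpcr$target_ct - qpcr$ref_ct
  out <- list()
  for (tg in unique(qpcr$target)) {
    sub <- qpcr[qpcr$target == tg, , drop = FALSE]
    cal_dct <- mean(sub$dct[sub$tissue == calibrator])
    for (ts in unique(sub$tissue)) {
      fc <- 2^(-(sub$dct[sub$tissue == ts] - cal_dct))
      s <- if (spread == "sd") stats::sd(fc)
           else stats::sd(fc) / sqrt(length(fc))
      out[[length(out) + 1L]] <- data.frame(
        target = tg, tissue = ts, fold_change = mean(fc), spread = s,
        n = length(fc), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write named candidates as GFF3
#'
#' @param candidates named candidate data.frame from [find_novel_mirnas()].
#' @param path output file.
#' @export
write_candidates_gff3 <- function(candidates, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(candidates))) {
    cc <- candidates[i, ]
    lines <- c(lines, sprintf(
      "%s\tsrnakit\tpre_miRNA\t%d\t%d\t.\t%s\t.\tID=%s",
      cc$chrom, cc$start + 1L, cc$end, cc$strand, cc$name))
  }
  writeLines(lines, path)
  invisible(lines)
}
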