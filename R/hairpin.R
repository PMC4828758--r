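#' Cluster genome alignments of candidate tags
#'
#' Merges same-strand alignment intervals whose gap is at most `merge_gap`
#' nt into genomic clusters (IRanges reduction per strand). Each cluster's
#' mature anchor is its highest-count tag (ties: lexicographically smallest
#' tag sequence).
#'
#' @param alignments data.frame of genome alignments with `tag_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`.
#' @param tags collapsed tag data.frame (for counts and sequences).
#' @param merge_gap maximum gap (nt) merged into one cluster.
#' @return data.frame of clusters: `cluster_id`, `chrom`, `start`, `end`,
#'   `strand`, `anchor_tag`, `anchor_start`, `anchor_end`, `n_tags`, plus a
#'   `members` list-column of per-cluster alignment data.frames.
#' @export
cluster_tags <- function(alignments, tags, merge_gap = 10L) {
  if (nrow(alignments) == 0L)
    return(data.frame(cluster_id = character(0)))
  counts <- stats::setNames(tags$count, tags$tag_id)
  seqs <- stats::setNames(tags$sequence, tags$tag_id)
  out <- list()
  for (str in unique(alignments$strand)) {
    a <- alignments[alignments$strand == str, , drop = FALSE]
    ir <- IRanges::IRanges(start = a$start + 1L, end = a$end)
    red <- IRanges::reduce(ir, min.gapwidth = merge_gap + 1L)
    ov <- IRanges::findOverlaps(ir, red)
    for (ci in seq_along(red)) {
      mem <- a[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == ci], ,
               drop = FALSE]
      cnt <- counts[mem$tag_id]
      ord <- order(-cnt, seqs[mem$tag_id], mem$start)
      anchor <- mem[ord[1], ]
      out[[length(out) + 1L]] <- data.frame(
        chrom = anchor$chrom,
        start = min(mem$start), end = max(mem$end), strand = str,
        anchor_tag = anchor$tag_id,
        anchor_start = anchor$start, anchor_end = anchor$end,
        n_tags = length(unique(mem$tag_id)),
        stringsAsFactors = FALSE)
      attr(out[[length(out)]], "members") <- mem
    }
  }
  members <- lapply(out, attr, "members")
  res <- do.call(rbind, out)
  o <- order(res$chrom, res$start, res$strand)
  res <- res[o, , drop = FALSE]
  res$cluster_id <- sprintf("cluster%d", seq_len(nrow(res)))
  res$members <- members[o]
  rownames(res) <- NULL
  res
}

#' Excise candidate precursor windows around a cluster anchor
#'
#' Two windows per cluster, covering the two arm hypotheses: window A treats
#' the anchor as the 5p arm (`[anchor_start - 20, anchor_end + flank)`),
#' window B as the 3p arm (`[anchor_start - flank, anchor_end + 20)`).
#' Windows are truncated (and flagged) at chromosome edges. Minus-strand
#' clusters are reverse-complemented so the mature read is always 5'->3' in
#' the window.
#'
#' @param genome genome DNA string.
#' @param cluster one row of [cluster_tags()] output.
#' @param flank distal flank length (nt).
#' @return list of two window records: `seq` (RNA, window orientation),
#'   `g_start`, `g_end` (0-based half-open genomic), `strand`,
#'   `anchor_in_window` (1-based inclusive interval of the anchor tag in
#'   window coordinates), `truncated`, `arm_hypothesis`.
#' @export
excise_windows <- function(genome, cluster, flank = 150L) {
  glen <- nchar(genome)
  mk <- function(ws, we, hyp) {
    trunc <- ws < 0L || we > glen
    ws <- max(0L, ws); we <- min(glen, we)
    sub <- substr(genome, ws + 1L, we)
    if (cluster$strand == "+") {
      seq <- as_rna(sub)
      a1 <- cluster$anchor_start - ws + 1L
      a2 <- cluster$anchor_end - ws
    } else {
      seq <- revcomp_rna(as_rna(sub))
      a1 <- we - cluster$anchor_end + 1L
      a2 <- we - cluster$anchor_start
    }
    list(seq = seq, g_start = ws, g_end = we, strand = cluster$strand,
         anchor_in_window = c(a1, a2), truncated = trunc,
         arm_hypothesis = hyp)
  }
  if (cluster$strand == "+") {
    a <- mk(cluster$anchor_start - 20L, cluster$anchor_end + flank, "5p")
    b <- mk(cluster$anchor_start - flank, cluster$anchor_end + 20L, "3p")
  } else {
    # in window orientation the proximal/distal sides swap on the genome
    a <- mk(cluster$anchor_start - flank, cluster$anchor_end + 20L, "5p")
    b <- mk(cluster$anchor_start - 20L, cluster$anchor_end + flank, "3p")
  }
  list(a, b)
}

# map a member alignment's 5' start into window coordinates (1-based)
member_start_in_window <- function(member, window) {
  if (window$strand == "+") member$start - window$g_start + 1L
  else window$g_end - member$end + 1L
}

#' Evaluate a candidate window as a miRNA hairpin
#'
#' MIREAP-style criteria with progressive precursor excision: candidate
#' precursor subsequences anchored at the mature read and extending by
#' increasing amounts toward the distal flank are folded one by one, and
#' the best subsequence satisfying the hairpin criteria is reported.
#' Helices shorter than `min_stack` stacked pairs are disregarded before
#' the criteria are applied (a maximum-pairing fold decorates random
#' sequence with isolated short helices). A candidate is accepted iff
#' (a) the mature's pairs form a single coherent duplex: one nested chain
#'     whose partners fall in a compact star region (at most the mature
#'     length plus `bulge_tol`),
#' (b) the mature lies on one arm: no self-pairing, no partners on both
#'     sides, and a terminal loop of at least 3 nt separating the arms,
#' (c) at least `min_pair_frac` of mature bases are paired, and
#' (d) at least `min_support` distinct tags start within `pos_tol` nt of
#'     the mature 5' end or of the star 5' end.
#'
#' @param window a window record from [excise_windows()].
#' @param mature_interval 1-based inclusive interval of the mature (anchor)
#'   within the window; defaults to the window's anchor.
#' @param support_starts integer vector: distinct supporting tags' 5' start
#'   positions in window coordinates (include the anchor itself).
#' @param min_pair_frac minimum fraction of mature bases paired.
#' @param min_support minimum distinct supporting tags at mature positions.
#' @param pos_tol tolerance (nt) around the mature/star 5' ends.
#' @param min_stack minimum stacked-pair run length retained.
#' @param bulge_tol extra width (nt) the star region may span beyond the
#'   mature length (bulges/asymmetric loops).
#' @param ext_step step (nt) between successive precursor extensions.
#' @return list: `accepted`, `flags` (unbranched, mature_in_one_arm,
#'   pairing_fraction_ok, support_ok), `precursor` (sequence),
#'   `pre_interval` (in window coords), `fold` (folded precursor),
#'   `mature_arm`, `mature_in_pre`, `star_in_pre` (precursor coords),
#'   `pairing_fraction`, `n_support`.
#' @export
evaluate_hairpin <- function(window, mature_interval = NULL,
                             support_starts = integer(0),
                             min_pair_frac = 0.6, min_support = 2L,
                             pos_tol = 3L, min_stack = 4L,
                             bulge_tol = 8L, ext_step = 5L) {
  if (is.null(mature_interval)) mature_interval <- window$anchor_in_window
  m1 <- mature_interval[1]; m2 <- mature_interval[2]
  m_len <- m2 - m1 + 1L
  wlen <- nchar(window$seq)
  no_flags <- c(unbranched = FALSE, mature_in_one_arm = FALSE,
                pairing_fraction_ok = FALSE, support_ok = FALSE)
  downstream <- window$arm_hypothesis == "5p"   # star lies 3' of the mature

  eval_sub <- function(s1, s2) {
    flags <- no_flags
    sub <- substr(window$seq, s1, s2)
    pf <- fold(sub)
    pairs <- filter_short_helices(pf$pairs, min_stack)
    lm1 <- m1 - s1 + 1L; lm2 <- m2 - s1 + 1L
    res <- list(accepted = FALSE, flags = flags, precursor = sub,
                pre_interval = c(s1, s2), fold = pf,
                mature_arm = NA_character_,
                mature_in_pre = c(lm1, lm2),
                star_in_pre = c(NA_integer_, NA_integer_),
                pairing_fraction = 0, n_support = 0L)
    if (nrow(pairs) == 0L) return(res)
    sel <- (pairs[, 1] >= lm1 & pairs[, 1] <= lm2) |
           (pairs[, 2] >= lm1 & pairs[, 2] <= lm2)
    mp <- pairs[sel, , drop = FALSE]
    if (nrow(mp) == 0L) return(res)
    partner <- ifelse(mp[, 1] >= lm1 & mp[, 1] <= lm2, mp[, 2], mp[, 1])
    up <- partner[partner < lm1]
    down <- partner[partner > lm2]
    internal <- partner[partner >= lm1 & partner <= lm2]
    side <- if (downstream) down else up
    minority <- if (downstream) up else down

    # (a) coherent duplex
    chain_ok <- is_single_stem(mp)
    compact_ok <- length(side) > 0L &&
      (max(side) - min(side) + 1L) <= m_len + bulge_tol
    flags["unbranched"] <- chain_ok && compact_ok

    # (b) one arm, with a real terminal loop
    loop_gap <- if (length(side) == 0L) -1L
                else if (downstream) min(side) - lm2 - 1L
                else lm1 - max(side) - 1L
    flags["mature_in_one_arm"] <- length(internal) == 0L &&
      length(minority) == 0L && loop_gap >= 3L

    # (c) mature pairing fraction
    in_m <- unique(c(mp[, 1], mp[, 2]))
    frac <- sum(in_m >= lm1 & in_m <= lm2) / m_len
    flags["pairing_fraction_ok"] <- frac >= min_pair_frac

    # star interval with the canonical 2-nt 3' overhang
    star <- c(NA_integer_, NA_integer_)
    arm <- NA_character_
    if (length(side)) {
      arm <- if (downstream) "5p" else "3p"
      star <- if (downstream)
        c(min(side), min(max(side) + 2L, nchar(sub)))
      else c(min(side), max(side) + 2L)
      star[2] <- min(star[2], nchar(sub))
    }

    # (d) read support at mature or star 5' positions (window coords)
    anchors <- m1
    if (!is.na(star[1])) anchors <- c(anchors, star[1] + s1 - 1L)
    n_support <- sum(vapply(unique(support_starts), function(s)
      any(abs(s - anchors) <= pos_tol), logical(1)))
    flags["support_ok"] <- n_support >= min_support

    res$flags <- flags
    res$accepted <- all(flags)
    res$mature_arm <- arm
    res$star_in_pre <- star
    res$pairing_fraction <- frac
    res$n_support <- n_support
    res
  }

  # progressive extensions: loop + star + overhangs span roughly
  # m_len + 14 .. m_len + 50 nt beyond the mature
  exts <- seq(m_len + 12L, m_len + 52L, by = ext_step)
  best <- NULL
  for (ext in exts) {
    if (downstream) {
      s1 <- max(1L, m1 - 3L); s2 <- min(wlen, m2 + ext)
    } else {
      s1 <- max(1L, m1 - ext); s2 <- min(wlen, m2 + 3L)
    }
    ev <- eval_sub(s1, s2)
    key <- c(sum(ev$flags), ev$pairing_fraction)
    if (is.null(best) || key[1] > best$key[1] ||
        (key[1] == best$key[1] && key[2] > best$key[2])) {
      best <- ev
      best$key <- key
    }
    if (best$accepted && best$pairing_fraction == 1) break
  }
  best$key <- NULL
  best
}

#' Name accepted candidates
#'
#' Sorts candidates by descending total supporting read count and assigns
#' names Novel-1, Novel-2, ...; candidates sharing an identical mature
#' sequence from distinct loci share a number and get letter suffixes
#' (a = higher count). Deterministic under input permutation.
#'
#' @param candidates data.frame with at least `mature_seq`, `total_count`
#'   and a locus key (`chrom`, `start`).
#' @return the data.frame, sorted, with a `name` column.
#' @export
name_candidates <- function(candidates) {
  if (nrow(candidates) == 0L) {
    candidates$name <- character(0)
    return(candidates)
  }
  o <- order(-candidates$total_count, candidates$mature_seq,
             candidates$chrom, candidates$start)
  cand <- candidates[o, , drop = FALSE]
  num <- integer(nrow(cand))
  seen <- character(0)
  for (i in seq_len(nrow(cand))) {
    hit <- match(cand$mature_seq[i], seen)
    if (is.na(hit)) {
      seen <- c(seen, cand$mature_seq[i])
      num[i] <- length(seen)
    } else num[i] <- hit
  }
  name <- sprintf("Novel-%d", num)
  for (k in unique(num[duplicated(num)])) {
    idx <- which(num == k)  # already in descending-count order
    name[idx] <- sprintf("Novel-%d%s", k, letters[seq_along(idx)])
  }
  cand$name <- name
  rownames(cand) <- NULL
  cand
}

#' Discover novel miRNA candidates
#'
#' Full hairpin-discovery pass: cluster the genome alignments of
#' novel-input tags, excise both arm-hypothesis windows per cluster,
#' evaluate each as a hairpin, keep the best accepted window per cluster,
#' and name the results.
#'
#' @param tags collapsed tag data.frame.
#' @param alignments novel-input genome alignments (from [classify_tags()]).
#' @param genome genome DNA string.
#' @param merge_gap cluster merge gap (nt).
#' @param flank distal window flank (nt).
#' @param ... thresholds passed to [evaluate_hairpin()].
#' @return named candidate data.frame: `name`, `chrom`, `start`, `end`,
#'   `strand`, `mature_seq`, `mature_arm`, `precursor_seq`, `structure`,
#'   `total_count`, `n_support_tags`, plus `supporting` list-column
#'   (tag_id, count, start_in_window).
#' @export
find_novel_mirnas <- function(tags, alignments, genome,
                              merge_gap = 10L, flank = 150L, ...) {
  empty <- data.frame(name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mature_seq = character(0),
                      mature_arm = character(0),
                      precursor_seq = character(0),
                      structure = character(0), total_count = numeric(0),
                      n_support_tags = integer(0), stringsAsFactors = FALSE)
  if (is.null(alignments) || nrow(alignments) == 0L) return(empty)
  clusters <- cluster_tags(alignments, tags, merge_gap)
  counts <- stats::setNames(tags$count, tags$tag_id)
  seqs <- stats::setNames(tags$sequence, tags$tag_id)
  rows <- list()
  for (ci in seq_len(nrow(clusters))) {
    cl <- clusters[ci, ]
    mem <- cl$members[[1]]
    windows <- excise_windows(genome, cl, flank)
    best <- NULL
    for (w in windows) {
      starts <- vapply(seq_len(nrow(mem)), function(k)
        member_start_in_window(mem[k, ], w), integer(1))
      names(starts) <- mem$tag_id
      starts <- starts[!duplicated(seqs[mem$tag_id])]
      ev <- evaluate_hairpin(w, support_starts = starts, ...)
      if (ev$accepted &&
          (is.null(best) || ev$pairing_fraction > best$ev$pairing_fraction))
        best <- list(w = w, ev = ev, starts = starts)
    }
    if (is.null(best)) next
    w <- best$w; ev <- best$ev
    sup_tags <- mem$tag_id[!duplicated(seqs[mem$tag_id])]
    # candidate mature is the genomic sequence under the anchor alignment
    # (the anchor tag may carry a mapping mismatch)
    mat_seq <- substr(w$seq, w$anchor_in_window[1], w$anchor_in_window[2])
    rows[[length(rows) + 1L]] <- {
      df <- data.frame(
        chrom = cl$chrom, start = cl$start, end = cl$end,
        strand = cl$strand, mature_seq = mat_seq,
        mature_arm = ev$mature_arm, precursor_seq = ev$precursor,
        structure = ev$fold$structure,
        total_count = sum(counts[sup_tags]),
        n_support_tags = length(sup_tags), stringsAsFactors = FALSE)
      df$supporting <- list(data.frame(tag_id = sup_tags,
                                       count = counts[sup_tags],
                                       start_in_window = best$starts,
                                       stringsAsFactors = FALSE))
      df
    }
  }
  if (length(rows) == 0L) return(empty)
  name_candidates(do.call(rbind, rows))
}
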