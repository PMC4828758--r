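# Independent oracles used across the suite. These deliberately share no
# code with the package implementation: folding is checked by explicit
# enumeration of every nested structure, matching by a plain R scan over
# every offset, and duplex alignment by a second, loop-based DP.

oracle_pair_weight <- function(a, b, wGC = 3, wAU = 2, wGU = 1) {
  ab <- paste0(a, b)
  if (ab %in% c("GC", "CG")) return(wGC)
  if (ab %in% c("AU", "UA")) return(wAU)
  if (ab %in% c("GU", "UG")) return(wGU)
  0
}

# maximum total pair weight over all nested structures, by exhaustive
# recursion on "what does position i do": unpaired, or paired with each
# admissible j. Exponential; only for length <= 14.
oracle_fold_max <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)  # i unpaired
    for (k in (i + min_loop + 1):j) {
      w <- oracle_pair_weight(ch[i], ch[k])
      if (w > 0) {
        v <- w + rec(i + 1, k - 1) + if (k < j) rec(k + 1, j) else 0
        if (v > best) best <- v
      }
    }
    best
  }
  n <- length(ch)
  if (n < min_loop + 2) return(0)
  rec(1, n)
}

# all ungapped genome alignments with <= max_mm substitutions: exhaustive
# scan over every offset and strand, vectorized over offsets (every offset
# is evaluated; nothing is pruned)
oracle_genome_scan <- function(tag, genome, max_mm = 1L) {
  tc <- utf8ToInt(srnakit::as_dna(tag))
  gc <- utf8ToInt(srnakit::as_dna(genome))
  lt <- length(tc); lg <- length(gc)
  rc <- rev(utf8ToInt(chartr("ACGT", "TGCA",
                             srnakit::as_dna(tag))))
  n_off <- lg - lt + 1L
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") tc else rc
    mm <- integer(n_off)
    for (l in seq_len(lt))
      mm <- mm + (gc[l:(l + n_off - 1L)] != pat[l])
    keep <- which(mm <= max_mm)
    if (length(keep))
      hits[[strand]] <- data.frame(start = keep - 1L, strand = strand,
                                   n_mismatches = mm[keep],
                                   stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(start = integer(0), strand = character(0),
                      n_mismatches = integer(0)))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

# best containment hit in reference order / offset order, plain R
oracle_ref_match <- function(tag, refs, max_mm = 1L) {
  tc <- strsplit(srnakit::as_rna(tag), "")[[1]]
  best <- NULL
  for (ri in seq_along(refs)) {
    rc <- strsplit(srnakit::as_rna(refs[[ri]]), "")[[1]]
    if (length(rc) < length(tc)) next
    for (off in 0:(length(rc) - length(tc))) {
      mm <- sum(rc[off + seq_along(tc)] != tc)
      if (mm <= max_mm && (is.null(best) || mm < best$n_mismatches))
        best <- list(reference_id = names(refs)[ri], n_mismatches = mm,
                     offset = off)
    }
  }
  best
}

# multiloop detection by explicit parse tree: a structure is branched iff
# some paired node has two or more paired children
oracle_is_unbranched <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  # children counts via a stack of open pairs; root is virtual
  paired_children <- c(0L)  # stack; top = current enclosing pair
  for (c in ch) {
    if (c == "(") {
      paired_children[length(paired_children)] <-
        paired_children[length(paired_children)] + 1L
      paired_children <- c(paired_children, 0L)
    } else if (c == ")") {
      if (paired_children[length(paired_children)] >= 2L) return(FALSE)
      paired_children <- paired_children[-length(paired_children)]
    }
  }
  TRUE
}

# independent duplex DP: plain recursive memoized alignment with the same
# scoring contract as align_duplex (miRNA global, UTR overhangs free)
oracle_duplex_score <- function(mirna, utr_window,
                                scores = srnakit::duplex_scores()) {
  a <- strsplit(srnakit::as_rna(mirna), "")[[1]]
  b <- rev(strsplit(srnakit::as_rna(utr_window), "")[[1]])
  n <- length(a); m <- length(b)
  pk <- function(x, y) {
    xy <- paste0(x, y)
    if (xy %in% c("AU", "UA", "CG", "GC")) "wc"
    else if (xy %in% c("GU", "UG")) "gu" else "none"
  }
  sc <- function(i, j) {
    k <- pk(a[i], b[j])
    s <- if (k == "wc") scores$wc else if (k == "gu") scores$gu
         else scores$mismatch
    if (k != "gu" && i >= scores$seed_range[1] && i <= scores$seed_range[2])
      s <- s * scores$seed_scale
    s
  }
  NEG <- -1e9
  M <- array(NEG, c(n + 1, m + 1)); X <- array(NEG, c(n + 1, m + 1))
  Y <- array(NEG, c(n + 1, m + 1))
  M[1, 1] <- 0
  X[1, 2:(m + 1)] <- 0
  for (i in seq_len(n)) Y[i + 1, 1] <-
    scores$gap_open + scores$gap_extend * (i - 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sc(i, j)
    X[i + 1, j + 1] <- max(M[i + 1, j] + scores$gap_open,
                           X[i + 1, j] + scores$gap_extend)
    Y[i + 1, j + 1] <- max(M[i, j + 1] + scores$gap_open,
                           Y[i, j + 1] + scores$gap_extend)
  }
  best <- NEG
  for (j in 0:m) best <- max(best, M[n + 1, j + 1], Y[n + 1, j + 1])
  best
}

# brute-force best end-anchored tag/canonical alignment over all offset
# pairs (for isomir module checks)
oracle_align_canonical <- function(tag, canonical, max_offset = 5L) {
  tc <- strsplit(tag, "")[[1]]; cc <- strsplit(canonical, "")[[1]]
  lt <- length(tc); lc <- length(cc)
  best <- NULL
  for (o5 in -max_offset:max_offset) {
    o3 <- lt - lc - o5
    if (abs(o3) > max_offset) next
    c_from <- max(1, 1 - o5); c_to <- min(lc, lc + o3)
    if (c_from > c_to) next
    idx <- c_from:c_to
    mm <- sum(cc[idx] != tc[idx + o5])
    better <- is.null(best) || mm < best$mm ||
      (mm == best$mm && (abs(o5) < abs(best$o5) ||
                         (abs(o5) == abs(best$o5) && abs(o3) < abs(best$o3))))
    if (better) best <- list(o5 = o5, o3 = o3, mm = mm)
  }
  best
}

random_rna_str <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# small simulated library shared by several tests
tiny_sim <- function(seed = 7, n_reads = 2000, ...) {
  simulate_library(sim_config(rng_seed = seed, n_reads = n_reads, ...))
}
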