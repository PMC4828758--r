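#' Nearest-neighbor RNA duplex stacking table
#'
#' Turner-style free-energy increments (kcal/mol, 37 C) for stacking two
#' adjacent base pairs in an RNA duplex, indexed as
#' `stack_table["XY", "X'Y'"]` where the top strand runs 5'-XY-3' over the
#' paired bottom strand 3'-X'Y'-5'; here indexed by the two pairs
#' (`"AU"`, `"UA"`, `"CG"`, `"GC"`, `"GU"`, `"UG"`), first pair 5' on the
#' top strand. Watson-Crick entries are the published nearest-neighbor
#' values; G:U entries are the published wobble increments.
#'
#' @return 6x6 numeric matrix of stacking energies.
#' @export
nn_stack_table <- function() {
  p <- c("AU", "UA", "CG", "GC", "GU", "UG")
  m <- matrix(NA_real_, 6, 6, dimnames = list(p, p))
  set <- function(a, b, v) {
    m[a, b] <<- v
    # a 5'->3' stack read from the other strand: reversed, pairs swapped
    m[rev_pair(b), rev_pair(a)] <<- v
  }
  rev_pair <- function(x) paste0(substr(x, 2, 2), substr(x, 1, 1))
  # Watson-Crick / Watson-Crick
  set("AU", "AU", -0.93); set("AU", "UA", -1.10); set("UA", "AU", -1.33)
  set("CG", "AU", -2.11); set("CG", "UA", -2.08)
  set("GC", "AU", -2.35); set("GC", "UA", -2.24)
  set("CG", "GC", -2.36); set("GC", "CG", -3.42); set("GC", "GC", -3.26)
  set("CG", "CG", -3.26)  # = GG/CC read from the other strand
  set("UA", "UA", -0.93); set("AU", "GC", -2.24); set("AU", "CG", -2.08)
  set("UA", "GC", -2.11); set("UA", "CG", -2.35)
  # wobble-containing stacks
  set("AU", "GU", -0.55); set("AU", "UG", -1.36)
  set("CG", "GU", -1.41); set("CG", "UG", -2.11)
  set("GC", "GU", -1.53); set("GC", "UG", -2.51)
  set("GU", "AU", -1.27); set("UG", "AU", -1.00)
  set("GU", "GC", -2.11); set("UG", "GC", -1.41)
  set("GU", "CG", -2.51); set("UG", "CG", -1.53)
  set("GU", "UA", -1.36); set("UG", "UA", -0.55)
  set("GU", "GU", -0.50); set("GU", "UG", 1.29)
  set("UG", "GU", 0.30); set("UG", "UG", -0.50)
  m
}

duplex_init_energy <- 4.1   # duplex initiation, kcal/mol
loop_penalty <- 4.0         # per interior loop / bulge, kcal/mol

pair_kind <- function(a, b) {
  ab <- paste0(a, b)
  if (ab %in% c("AU", "UA", "CG", "GC")) return("wc")
  if (ab %in% c("GU", "UG")) return("gu")
  "none"
}

#' Find canonical seed-match sites for a miRNA in a 3'UTR
#'
#' Scans the UTR for reverse-complement matches to miRNA positions 2-7
#' (6mer) and upgrades each occurrence: position-8 match adds m8 (7mer-m8),
#' an A opposite position 1 adds A1 (7mer-A1), both give an 8mer. Seed
#' matching is Watson-Crick only. Every occurrence is reported.
#'
#' @param mirna miRNA sequence (RNA, 5'->3').
#' @param utr 3'UTR sequence (RNA, 5'->3').
#' @return data.frame: `start`, `end` (1-based inclusive interval of the
#'   matched site in the UTR), `site_type`, `seed_start` (start of the
#'   6mer core).
#' @export
find_seed_sites <- function(mirna, utr) {
  mirna <- as_rna(mirna); utr <- as_rna(utr)
  check_that(nchar(mirna) >= 8L, "miRNA must be >= 8 nt")
  core <- revcomp_rna(substr(mirna, 2L, 7L))  # matches miRNA 2-7
  m8 <- chartr("ACGU", "UGCA", substr(mirna, 8L, 8L))
  lu <- nchar(utr)
  out <- list()
  if (lu < 6L) return(data.frame(start = integer(0), end = integer(0),
                                 site_type = character(0),
                                 seed_start = integer(0)))
  for (i in seq_len(lu - 5L)) {
    if (substr(utr, i, i + 5L) != core) next
    # UTR is 5'->3'; the miRNA lies antiparallel, so position 8 pairs the
    # base 5' of the core match and position 1 faces the base 3' of it
    has_m8 <- i > 1L && substr(utr, i - 1L, i - 1L) == m8
    has_a1 <- i + 6L <= lu && substr(utr, i + 6L, i + 6L) == "A"
    type <- if (has_m8 && has_a1) "8mer"
            else if (has_m8) "7mer-m8"
            else if (has_a1) "7mer-A1"
            else "6mer"
    st <- if (has_m8) i - 1L else i
    en <- if (has_a1) i + 6L else i + 5L
    out[[length(out) + 1L]] <- data.frame(start = st, end = en,
                                          site_type = type, seed_start = i,
                                          stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      site_type = character(0), seed_start = integer(0)))
  do.call(rbind, out)
}

#' Duplex alignment scoring scheme
#'
#' Position-dependent complementarity scores for [align_duplex()]:
#' Watson-Crick pair, G:U wobble, mismatch and affine gap scores, with
#' match/mismatch scores in the miRNA seed region scaled (miRanda-style) so
#' seed pairing dominates the alignment.
#'
#' @param wc,gu,mismatch per-column pair scores.
#' @param gap_open,gap_extend affine gap penalties.
#' @param seed_scale multiplier applied to non-wobble scores at seed
#'   positions.
#' @param seed_range miRNA positions treated as seed (1-based, inclusive).
#' @return a list of scoring parameters.
#' @export
duplex_scores <- function(wc = 5, gu = 2, mismatch = -3,
                          gap_open = -8, gap_extend = -2,
                          seed_scale = 4, seed_range = c(2L, 8L)) {
  list(wc = wc, gu = gu, mismatch = mismatch, gap_open = gap_open,
       gap_extend = gap_extend, seed_scale = seed_scale,
       seed_range = seed_range)
}

#' Align a miRNA against a UTR window as an RNA duplex
#'
#' Affine-gap alignment of the miRNA (5'->3') against the reverse of the
#' UTR window, scoring complementarity rather than identity: +5 per
#' Watson-Crick pair, +2 per G:U wobble, -3 per mismatch, -8/-2 gap
#' open/extend, with match/mismatch scores in the miRNA seed region
#' (positions 2-8) scaled x4 so seed pairing dominates, and 3'-supplementary
#' pairing contributing at unscaled weight. The miRNA is aligned end to end;
#' overhanging UTR bases at either end of the window are free (the window is
#' allowed to be larger than the duplex). Returns the three-line rendering
#' with `|` for Watson-Crick pairs, `:` for G:U wobbles and `-` for gaps.
#'
#' @param mirna miRNA sequence (RNA, 5'->3').
#' @param utr_window UTR subsequence (RNA, 5'->3') covering the site and
#'   enough upstream sequence for the miRNA 3' end (internal gaps bounded by
#'   the window size).
#' @param scores scoring scheme from `duplex_scores()`.
#' @return list of class `duplex_alignment`: `score`, `mirna_aln`,
#'   `utr_aln` (aligned strings, miRNA 5'->3' and UTR 3'->5'), `marks`
#'   (`|`/`:`/space per column), `pairs` (data.frame mirna_pos, utr_pos,
#'   kind), `rendering` (three-line string, UTR printed 5'->3' on top).
#' @export
align_duplex <- function(mirna, utr_window, scores = duplex_scores()) {
  mirna <- as_rna(mirna); utr <- as_rna(utr_window)
  check_that(nchar(utr) >= 6L, "UTR window shorter than a seed match")
  a <- seq_chars(mirna)                  # rows: miRNA 5'->3'
  b <- rev(seq_chars(utr))               # cols: UTR 3'->5' (antiparallel)
  n <- length(a); m <- length(b)
  sc <- function(i, j) {
    k <- pair_kind(a[i], b[j])
    s <- switch(k, wc = scores$wc, gu = scores$gu, scores$mismatch)
    if (k != "gu" && i >= scores$seed_range[1] && i <= scores$seed_range[2])
      s <- s * scores$seed_scale
    s
  }
  NEG <- -1e9
  # states: M = (mis)paired column, X = unopposed UTR base, Y = unopposed
  # miRNA base; leading/trailing X runs are free (UTR overhang)
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  pM <- matrix(NA_character_, n + 1L, m + 1L)
  pX <- matrix(NA_character_, n + 1L, m + 1L)
  pY <- matrix(NA_character_, n + 1L, m + 1L)
  M[1, 1] <- 0
  for (j in seq_len(m)) { X[1, j + 1L] <- 0; pX[1, j + 1L] <- "free" }
  for (i in seq_len(n)) {
    Y[i + 1L, 1] <- scores$gap_open + scores$gap_extend * (i - 1L)
    pY[i + 1L, 1] <- if (i == 1L) "M" else "Y"
  }
  argmax3 <- function(vals) c("M", "X", "Y")[which.max(vals)]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sc(i, j)
      vals <- c(M[i, j], X[i, j], Y[i, j])
      M[i + 1L, j + 1L] <- max(vals) + s
      pM[i + 1L, j + 1L] <- argmax3(vals)
      vx <- c(M[i + 1L, j] + scores$gap_open,
              X[i + 1L, j] + scores$gap_extend)
      X[i + 1L, j + 1L] <- max(vx)
      pX[i + 1L, j + 1L] <- c("M", "X")[which.max(vx)]
      vy <- c(M[i, j + 1L] + scores$gap_open,
              Y[i, j + 1L] + scores$gap_extend)
      Y[i + 1L, j + 1L] <- max(vy)
      pY[i + 1L, j + 1L] <- c("M", "Y")[which.max(vy)]
    }
  }
  # trailing UTR overhang is free: end anywhere in the last row
  end_best <- NEG; end_j <- m; end_state <- "M"
  for (j in 0:m) {
    for (st in c("M", "Y")) {
      v <- if (st == "M") M[n + 1L, j + 1L] else Y[n + 1L, j + 1L]
      if (v > end_best) { end_best <- v; end_j <- j; end_state <- st }
    }
  }
  score <- end_best
  cols <- list()
  # unaligned trailing UTR bases (window overhang), rendered as context
  if (end_j < m) for (j in m:(end_j + 1L))
    cols[[length(cols) + 1L]] <- c("-", b[j], "overhang")
  i <- n; j <- end_j; state <- end_state
  while (i > 0L || j > 0L) {
    if (state == "M") {
      cols[[length(cols) + 1L]] <- c(a[i], b[j], "pair")
      state <- pM[i + 1L, j + 1L]
      i <- i - 1L; j <- j - 1L
      if (i == 0L && j == 0L) break
    } else if (state == "X") {
      if (identical(pX[i + 1L, j + 1L], "free")) {
        # leading UTR overhang: consume remaining UTR bases freely
        while (j > 0L) {
          cols[[length(cols) + 1L]] <- c("-", b[j], "overhang")
          j <- j - 1L
        }
        break
      }
      cols[[length(cols) + 1L]] <- c("-", b[j], "gap_mirna")
      state <- pX[i + 1L, j + 1L]
      j <- j - 1L
    } else {
      cols[[length(cols) + 1L]] <- c(a[i], "-", "gap_utr")
      state <- pY[i + 1L, j + 1L]
      i <- i - 1L
    }
    if (i == 0L && j > 0L && state != "X") state <- "X"
  }
  cols <- rev(cols)
  top <- vapply(cols, `[`, character(1), 1)   # miRNA 5'->3'
  bot <- vapply(cols, `[`, character(1), 2)   # UTR 3'->5'
  marks <- vapply(seq_along(cols), function(k) {
    if (top[k] == "-" || bot[k] == "-") return(" ")
    switch(pair_kind(top[k], bot[k]), wc = "|", gu = ":", " ")
  }, character(1))
  # pair list in original coordinates
  ti <- cumsum(top != "-"); bj <- cumsum(bot != "-")
  pr <- which(marks != " ")
  pairs <- data.frame(mirna_pos = ti[pr],
                      utr_pos = nchar(utr) - bj[pr] + 1L,
                      kind = ifelse(marks[pr] == "|", "wc", "gu"),
                      stringsAsFactors = FALSE)
  rendering <- paste0(
    "5' ", paste(rev(bot), collapse = ""), " 3' (UTR)\n",
    "   ", paste(rev(marks), collapse = ""), "\n",
    "3' ", paste(rev(top), collapse = ""), " 5' (miRNA)")
  structure(list(score = score, mirna_aln = paste(top, collapse = ""),
                 utr_aln = paste(bot, collapse = ""), marks = marks,
                 pairs = pairs, rendering = rendering),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(x$rendering, "\n", sprintf("score %.1f, %d pairs", x$score,
                                 nrow(x$pairs)), "\n", sep = "")
  invisible(x)
}

#' Parse a duplex rendering back into its pair classification
#'
#' Round-trip check support: re-derives the per-column pair kinds from the
#' three-line rendering.
#'
#' @param rendering three-line string from [align_duplex()].
#' @return data.frame with `column`, `top`, `bottom`, `kind`.
#' @export
parse_duplex_rendering <- function(rendering) {
  ln <- strsplit(rendering, "\n", fixed = TRUE)[[1]]
  utr <- seq_chars(sub(" 3' \\(UTR\\)$", "", sub("^5' ", "", ln[1])))
  mk <- seq_chars(substr(ln[2], 4L, 3L + length(utr)))
  mir <- seq_chars(sub(" 5' \\(miRNA\\)$", "", sub("^3' ", "", ln[3])))
  kind <- ifelse(mk == "|", "wc", ifelse(mk == ":", "gu",
                 ifelse(utr == "-" | mir == "-", "gap", "mismatch")))
  data.frame(column = seq_along(utr), top = utr, bottom = mir, kind = kind,
             stringsAsFactors = FALSE)
}

#' Duplex free energy from the aligned pair stack
#'
#' Sums published nearest-neighbor stacking increments over consecutively
#' stacked pairs of the duplex alignment, adds a +4 kcal/mol penalty per
#' interior loop or bulge (any unpaired stretch between helices) and the
#' +4.1 kcal/mol duplex initiation term. An alignment with no pairs has
#' energy 0.
#'
#' @param alignment a `duplex_alignment` from [align_duplex()].
#' @return energy in kcal/mol.
#' @export
duplex_energy <- function(alignment) {
  marks <- alignment$marks
  paired_cols <- which(marks != " ")
  if (length(paired_cols) == 0L) return(0)
  tab <- nn_stack_table()
  top <- seq_chars(alignment$mirna_aln)
  bot <- seq_chars(alignment$utr_aln)
  e <- duplex_init_energy
  for (k in seq_along(paired_cols)[-1]) {
    c1 <- paired_cols[k - 1L]; c2 <- paired_cols[k]
    if (c2 == c1 + 1L) {
      p1 <- paste0(top[c1], bot[c1])
      p2 <- paste0(top[c2], bot[c2])
      e <- e + tab[p1, p2]
    } else {
      e <- e + loop_penalty
    }
  }
  e
}

#' Score, align and filter candidate target sites
#'
#' Extends each seed site to a duplex window covering the full miRNA,
#' aligns it, computes the duplex energy, and keeps sites with
#' `score >= min_score` and `energy <= max_energy`, sorted by (utr_id,
#' position).
#'
#' @param mirna miRNA sequence (RNA).
#' @param utr UTR sequence (RNA).
#' @param mirna_id,utr_id identifiers carried into the result.
#' @param min_score minimum alignment score retained.
#' @param max_energy maximum (most positive) duplex energy retained,
#'   kcal/mol.
#' @param scores duplex scoring scheme.
#' @return data.frame of retained `TargetSite` rows: `mirna_id`, `utr_id`,
#'   `start`, `end`, `site_type`, `score`, `energy`, `rendering`.
#' @export
scan_targets <- function(mirna, utr, mirna_id = "miRNA", utr_id = "UTR",
                         min_score = 140, max_energy = -14,
                         scores = duplex_scores()) {
  mirna <- as_rna(mirna); utr <- as_rna(utr)
  sites <- find_seed_sites(mirna, utr)
  if (nrow(sites) == 0L)
    return(data.frame(mirna_id = character(0), utr_id = character(0),
                      start = integer(0), end = integer(0),
                      site_type = character(0), score = numeric(0),
                      energy = numeric(0), rendering = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(sites)), function(k) {
    s <- sites[k, ]
    # duplex window: site plus upstream UTR opposite the miRNA 3' region
    w_end <- min(nchar(utr), s$seed_start + 6L)
    w_start <- max(1L, s$seed_start - (nchar(mirna) - 7L) - 4L)
    aln <- align_duplex(mirna, substr(utr, w_start, w_end), scores)
    data.frame(mirna_id = mirna_id, utr_id = utr_id, start = s$start,
               end = s$end, site_type = s$site_type, score = aln$score,
               energy = duplex_energy(aln), rendering = aln$rendering,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$score >= min_score & out$energy <= max_energy, ,
             drop = FALSE]
  out <- out[order(out$utr_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
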