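#' Fold an RNA sequence (weighted Nussinov)
#'
#' Maximum-weight nested base pairing by dynamic programming: pairs are
#' A-U, G-C and G-U with configurable weights, a hairpin loop must span at
#' least `min_loop` unpaired bases, and pseudoknots are excluded by
#' construction. Traceback is deterministic (pairing the interval ends is
#' preferred over leaving an end unpaired, which is preferred over
#' bifurcation at the largest split point), so identical input yields an
#' identical structure.
#'
#' This is a combinatorial stand-in for a thermodynamic folder, adequate for
#' hairpin-shape criteria at toy scale; the hairpin-evaluation code accepts
#' any folder with the same return shape.
#'
#' @param sequence RNA sequence (A/C/G/U).
#' @param min_loop minimum unpaired span inside a hairpin loop.
#' @param weights named numeric: pair weights `GC`, `AU`, `GU`.
#' @return object of class `fold_result`: `sequence`, `structure`
#'   (dot-bracket), `pairs` (2-column 1-based matrix, i < j), `score`.
#' @export
fold <- function(sequence, min_loop = 3L, weights = c(GC = 3, AU = 2, GU = 1)) {
  sequence <- as_rna(sequence)
  check_that(nchar(sequence) <= 1000L, "fold: sequence longer than 1000 nt")
  res <- nussinov_fold(sequence, as.integer(min_loop),
                       as.integer(weights[["GC"]]),
                       as.integer(weights[["AU"]]),
                       as.integer(weights[["GU"]]))
  pairs <- res$pairs
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(list(sequence = sequence, structure = res$structure,
                 pairs = pairs, score = res$score),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "  (score ", x$score, ", ",
      nrow(x$pairs), " pairs)\n", sep = "")
  invisible(x)
}

#' Parse a dot-bracket string into a pair list
#'
#' @param structure dot-bracket string using `(`, `)`, `.`.
#' @return 2-column matrix of 1-based pairs (i < j).
#' @export
dotbracket_pairs <- function(structure) {
  ch <- seq_chars(structure)
  check_that(all(ch %in% c("(", ")", ".")),
             "dot-bracket may contain only '(', ')' and '.'")
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  out <- vector("list", sum(ch == ")"))
  k <- 0L
  for (i in seq_along(ch)) {
    if (ch[i] == "(") open <- c(open, i)
    else if (ch[i] == ")") {
      if (length(open) == 0L)
        stop("unbalanced dot-bracket: unmatched ')'", call. = FALSE)
      k <- k + 1L
      out[[k]] <- c(open[length(open)], i)
      open <- open[-length(open)]
    }
  }
  if (length(open))
    stop("unbalanced dot-bracket: unmatched '('", call. = FALSE)
  if (k == 0L) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, out)
  m[order(m[, 1]), , drop = FALSE]
}

#' Test whether a structure is a single unbranched stem-loop family
#'
#' TRUE iff the pair set contains no multiloop: no pair encloses two
#' disjoint pairs. (Nested stems with interior loops and bulges pass;
#' any bifurcation under an enclosing pair fails.)
#'
#' @param structure dot-bracket string (or a `fold_result`).
#' @return logical.
#' @export
is_unbranched <- function(structure) {
  if (inherits(structure, "fold_result")) structure <- structure$structure
  pairs <- dotbracket_pairs(structure)
  n <- nrow(pairs)
  if (n <= 1L) return(TRUE)
  # pairs sorted by i; a multiloop exists iff some enclosing pair contains
  # two pairs that are disjoint from each other
  for (a in seq_len(n)) {
    ia <- pairs[a, 1]; ja <- pairs[a, 2]
    inside <- pairs[, 1] > ia & pairs[, 2] < ja
    idx <- which(inside)
    if (length(idx) >= 2L) {
      # disjoint children: a pair starting after another inside pair ends
      ends <- pairs[idx, 2]
      starts <- pairs[idx, 1]
      if (any(outer(ends, starts, `<`))) return(FALSE)
    }
  }
  TRUE
}

# TRUE iff every two pairs are nested one inside the other (single stem,
# possibly with interior loops/bulges); stricter than is_unbranched in that
# two disjoint external helices also fail.
is_single_stem <- function(pairs) {
  n <- nrow(pairs)
  if (n <= 1L) return(n == 1L)
  o <- order(pairs[, 1])
  i <- pairs[o, 1]; j <- pairs[o, 2]
  all(diff(i) > 0) && all(diff(j) < 0)
}

# drop helices (maximal runs of stacked pairs) shorter than min_stack pairs;
# Nussinov over-pairs random sequence with isolated 1-2 bp helices, which
# this filter removes before hairpin-shape criteria are applied.
filter_short_helices <- function(pairs, min_stack = 2L) {
  n <- nrow(pairs)
  if (n == 0L || min_stack <= 1L) return(pairs)
  o <- order(pairs[, 1])
  p <- pairs[o, , drop = FALSE]
  helix <- integer(n)
  h <- 1L
  helix[1] <- h
  for (r in 2:max(n, 2L)) {
    if (r > n) break
    stacked <- p[r, 1] == p[r - 1, 1] + 1L && p[r, 2] == p[r - 1, 2] - 1L
    if (!stacked) h <- h + 1L
    helix[r] <- h
  }
  keep <- helix %in% as.integer(names(which(table(helix) >= min_stack)))
  p[keep, , drop = FALSE]
}
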