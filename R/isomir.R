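#' Extract the seed of a mature miRNA
#'
#' The seed is positions 2-8 (1-based, inclusive) of the 5'->3' mature
#' sequence — the 7-mer that dominates target recognition; a 5' end shift
#' changes the seed frame.
#'
#' @param sequence mature sequence (RNA), length >= 8.
#' @return 7-nt seed string.
#' @export
extract_seed <- function(sequence) {
  check_that(all(nchar(sequence) >= 8L),
             "seed extraction requires length >= 8 nt")
  substr(as_rna(sequence), 2L, 8L)
}

#' Align a tag to its canonical mature sequence
#'
#' Ungapped, end-anchored alignment: over all 5'/3' end-offset pairs within
#' `max_offset` consistent with the tag length, choose the pair minimizing
#' substitutions in the overlapping core, ties broken by smallest |5'
#' offset| then smallest |3' offset|. Substitution positions are recorded in
#' canonical coordinates. Offsets are signed (negative = trimmed relative to
#' the canonical end, positive = extended).
#'
#' @param tag tag sequence (RNA).
#' @param canonical canonical mature sequence (RNA).
#' @param max_offset maximum |offset| at each end.
#' @param max_sub maximum substitutions; exceeding it is an assignment error.
#' @return list: `offset5`, `offset3`, `substitutions` (data.frame:
#'   `pos_canonical`, `pos_tag`, `from`, `to`, `in_seed`).
#' @export
align_to_canonical <- function(tag, canonical, max_offset = 5L,
                               max_sub = 2L) {
  tag <- as_rna(tag); canonical <- as_rna(canonical)
  lt <- nchar(tag); lc <- nchar(canonical)
  tc <- seq_chars(tag); cc <- seq_chars(canonical)
  best <- NULL
  for (o5 in seq(-max_offset, max_offset)) {
    o3 <- lt - lc - o5
    if (abs(o3) > max_offset) next
    # overlap in canonical coordinates
    c_from <- if (o5 < 0L) 1L - o5 else 1L
    c_to <- if (o3 < 0L) lc + o3 else lc
    if (c_from > c_to) next
    idx <- seq(c_from, c_to)
    t_idx <- idx + o5
    mm <- which(cc[idx] != tc[t_idx])
    cand <- list(offset5 = o5, offset3 = o3, n_sub = length(mm),
                 sub_c = idx[mm], sub_t = t_idx[mm])
    if (is.null(best) ||
        cand$n_sub < best$n_sub ||
        (cand$n_sub == best$n_sub &&
         (abs(o5) < abs(best$offset5) ||
          (abs(o5) == abs(best$offset5) && abs(o3) < abs(best$offset3)))))
      best <- cand
  }
  if (is.null(best) || best$n_sub > max_sub)
    stop("tag cannot be assigned to this miRNA within offset/substitution ",
         "bounds", call. = FALSE)
  subs <- data.frame(pos_canonical = best$sub_c, pos_tag = best$sub_t,
                     from = cc[best$sub_c], to = tc[best$sub_t],
                     in_seed = best$sub_c >= 2L & best$sub_c <= 8L,
                     stringsAsFactors = FALSE)
  if (best$n_sub == 0L) subs <- subs[0, , drop = FALSE]
  list(offset5 = best$offset5, offset3 = best$offset3,
       substitutions = subs)
}

#' Classify a tag as an isomiR variant
#'
#' Applies the 5'/internal/3' taxonomy: a 5' end offset makes an iso5
#' component, a 3' end offset an iso3 component, substitutions alone an
#' internal isomiR; edits at both ends (or ends plus substitutions) are
#' classed `mixed`. End extensions are templated iff every added base
#' matches the precursor/genomic flank; otherwise a 3' addition is
#' non-templated, with the added nucleotide recorded (A/U/other —
#' 3' adenylation and uridylation are the biologically prominent cases).
#'
#' @param tag tag sequence (RNA).
#' @param canonical canonical mature sequence (RNA).
#' @param context precursor-with-flanks sequence containing the canonical;
#'   required whenever an extension must be typed.
#' @param ctx_start 1-based start of canonical in context (located by exact
#'   match when NULL).
#' @param alignment optional precomputed [align_to_canonical()] result.
#' @param mirna_id,tag_id,count carried through into the record.
#' @return an `isomir_record` list: `mirna_id`, `tag_id`, `count`, `class`
#'   (canonical/iso5/iso3/internal/mixed), `subtype5`, `subtype3`,
#'   `added3`, `substitutions`, `offset5`, `offset3`, `templated`.
#' @export
classify_isomir <- function(tag, canonical, context = NULL,
                            ctx_start = NULL, alignment = NULL,
                            mirna_id = NA_character_,
                            tag_id = NA_character_, count = 1L) {
  tag <- as_rna(tag); canonical <- as_rna(canonical)
  if (is.null(alignment))
    alignment <- align_to_canonical(tag, canonical)
  o5 <- alignment$offset5; o3 <- alignment$offset3
  subs <- alignment$substitutions
  nsub <- nrow(subs)

  flank_up <- flank_down <- NULL
  if (!is.null(context)) {
    context <- as_rna(context)
    if (is.null(ctx_start)) {
      ctx_start <- as.integer(regexpr(canonical, context, fixed = TRUE))
      check_that(ctx_start > 0, "canonical not found in context")
    }
    ctx_end <- ctx_start + nchar(canonical) - 1L
    flank_up <- substr(context, max(1L, ctx_start - 8L), ctx_start - 1L)
    flank_down <- substr(context, ctx_end + 1L,
                         min(nchar(context), ctx_end + 8L))
  }

  templ <- NA
  subtype5 <- "none"; subtype3 <- "none"; added3 <- NA_character_
  if (o5 < 0L) subtype5 <- "trim"
  if (o5 > 0L) {
    if (is.null(flank_up))
      stop("precursor context required to type a 5' extension",
           call. = FALSE)
    added <- substr(tag, 1L, o5)
    tmpl <- substr(flank_up, nchar(flank_up) - o5 + 1L, nchar(flank_up))
    templ <- identical(added, tmpl)
    subtype5 <- if (templ) "ext_templated" else "ext_nontemplated"
  }
  if (o3 < 0L) subtype3 <- "trim"
  if (o3 > 0L) {
    if (is.null(flank_down))
      stop("precursor context required to type a 3' extension",
           call. = FALSE)
    added <- substr(tag, nchar(tag) - o3 + 1L, nchar(tag))
    tmpl <- substr(flank_down, 1L, o3)
    templ <- identical(added, tmpl)
    if (templ) subtype3 <- "ext_templated"
    else {
      subtype3 <- "add_nontemplated"
      u <- unique(seq_chars(added))
      added3 <- if (identical(u, "A")) "A"
                else if (identical(u, "U")) "U" else "other"
    }
  }

  has5 <- o5 != 0L; has3 <- o3 != 0L
  cls <- if (!has5 && !has3 && nsub == 0L) "canonical"
         else if (has5 && !has3 && nsub == 0L) "iso5"
         else if (!has5 && has3 && nsub == 0L) "iso3"
         else if (!has5 && !has3 && nsub > 0L) "internal"
         else "mixed"

  structure(list(mirna_id = mirna_id, tag_id = tag_id, count = count,
                 class = cls, subtype5 = subtype5, subtype3 = subtype3,
                 added3 = added3, substitutions = subs,
                 offset5 = o5, offset3 = o3, templated = templ),
            class = "isomir_record")
}

#' Build isomiR records for a set of tags against their miRNAs
#'
#' @param assignments data.frame with `tag_id`, `sequence`, `count`,
#'   `mirna_id`; one row per assigned tag.
#' @param canonicals named RNA vector of canonical matures (names =
#'   mirna_id).
#' @param contexts optional named RNA vector of precursor contexts.
#' @return data.frame of flattened records (one row per tag) with the
#'   fields of [classify_isomir()]; substitution positions collapsed to a
#'   comma string, plus `n_sub` and `n_sub_seed`.
#' @export
isomir_records <- function(assignments, canonicals, contexts = NULL) {
  rows <- lapply(seq_len(nrow(assignments)), function(i) {
    a <- assignments[i, ]
    ctx <- if (!is.null(contexts)) contexts[[a$mirna_id]] else NULL
    rec <- classify_isomir(a$sequence, canonicals[[a$mirna_id]],
                           context = ctx, mirna_id = a$mirna_id,
                           tag_id = a$tag_id, count = a$count)
    data.frame(mirna_id = rec$mirna_id, tag_id = rec$tag_id,
               count = rec$count, class = rec$class,
               subtype5 = rec$subtype5, subtype3 = rec$subtype3,
               added3 = rec$added3,
               offset5 = rec$offset5, offset3 = rec$offset3,
               templated = rec$templated,
               n_sub = nrow(rec$substitutions),
               n_sub_seed = sum(rec$substitutions$in_seed),
               sub_positions = paste(rec$substitutions$pos_canonical,
                                     collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize isomiR records
#'
#' Read-weighted class fractions over {canonical, iso5, iso3, internal,
#' mixed} (each read counted once), the trim share within 3' isomiRs, and
#' per-miRNA distinct isomiR counts split by arm (for ids suffixed -5p/-3p).
#' Tag-weighted fractions are reported alongside.
#'
#' @param records data.frame from [isomir_records()].
#' @return list: `class_fractions` (read-weighted), `class_fractions_tag`,
#'   `noncanonical_fractions` (over non-canonical reads), `iso3_trim_share`,
#'   `per_mirna` (mirna_id, arm, n_isomirs, reads).
#' @export
summarize_isomirs <- function(records) {
  check_that(nrow(records) > 0, "no isomiR records to summarize")
  lvls <- c("canonical", "iso5", "iso3", "internal", "mixed")
  cls <- factor(records$class, levels = lvls)
  w <- records$count
  cf <- tapply(w, cls, sum, default = 0) / sum(w)
  cft <- table(cls) / nrow(records)
  noncan <- cls != "canonical"
  ncf <- if (any(noncan))
    tapply(w[noncan], droplevels(cls[noncan]), sum, default = 0) /
      sum(w[noncan])
  else stats::setNames(numeric(0), character(0))
  iso3 <- records$class == "iso3"
  trim_share <- if (any(iso3))
    sum(w[iso3 & records$subtype3 == "trim"]) / sum(w[iso3])
  else NA_real_
  arm <- ifelse(grepl("-5p$", records$mirna_id), "5p",
                ifelse(grepl("-3p$", records$mirna_id), "3p", "unassigned"))
  per <- stats::aggregate(
    list(n_isomirs = records$tag_id, reads = records$count),
    by = list(mirna_id = records$mirna_id, arm = arm),
    FUN = function(x) if (is.numeric(x)) sum(x) else length(unique(x)))
  per$n_isomirs <- as.integer(per$n_isomirs)
  list(class_fractions = as.numeric(cf) |> stats::setNames(lvls),
       class_fractions_tag = as.numeric(cft) |> stats::setNames(lvls),
       noncanonical_fractions = ncf,
       iso3_trim_share = trim_share,
       per_mirna = per)
}
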