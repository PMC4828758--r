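#' isomiR generative rates
#'
#' Mixture weights for the variant classes emitted by [apply_isomir()]:
#' canonical reads, 3' trimming, 5' trimming, templated 3' extension,
#' non-templated 3' A/U addition, 1-nt 5' shift and internal single-base
#' substitution. Weights must sum to 1.
#'
#' @param p_canonical,p_trim3,p_trim5,p_ext3_templated,p_add3_nontemplated,p_shift5,p_substitution
#'   class probabilities (sum to 1).
#' @param add3_weights named weights for choosing A vs U in non-templated
#'   additions.
#' @param trim_step geometric step parameter for trim/extension lengths:
#'   length = 1 + rgeom(trim_step), capped so the product stays within the
#'   length filter and the offset cap.
#' @param max_offset maximum |end offset| the generator will emit.
#' @return an `isomir_rates` list.
#' @export
isomir_rates <- function(p_canonical = 0.55, p_trim3 = 0.20, p_trim5 = 0.05,
                         p_ext3_templated = 0.07, p_add3_nontemplated = 0.05,
                         p_shift5 = 0.03, p_substitution = 0.05,
                         add3_weights = c(A = 0.5, U = 0.5),
                         trim_step = 0.5, max_offset = 5L) {
  p <- c(canonical = p_canonical, trim3 = p_trim3, trim5 = p_trim5,
         ext3_templated = p_ext3_templated,
         add3_nontemplated = p_add3_nontemplated,
         shift5 = p_shift5, substitution = p_substitution)
  check_that(all(p >= 0 & p <= 1), "isomiR class rates must be in [0,1]")
  check_that(abs(sum(p) - 1) < 1e-8, "isomiR class rates must sum to 1")
  structure(list(p = p, add3_weights = add3_weights / sum(add3_weights),
                 trim_step = trim_step, max_offset = as.integer(max_offset)),
            class = "isomir_rates")
}

#' Simulation configuration
#'
#' Defines a ground-truth toy genome with embedded miRNA hairpins and the
#' synthetic small-RNA library read off it: a 3'-adapter-ligated mixture of
#' canonical miRNA reads, isomiR variants, ncRNA fragments and random
#' background, with an 18-30 nt dominated insert length distribution whose
#' mode is 22 nt.
#'
#' @param rng_seed integer seed; every downstream draw is reproducible from it.
#' @param genome_length toy genome length (nt).
#' @param n_mirna_genes number of hairpin precursors planted in the genome.
#' @param n_conserved_mirnas how many planted genes' mature sequences are
#'   handed to the annotator as the known ("conserved") mature set; remaining
#'   genes exercise novel discovery. Default: half the genes.
#' @param n_ncrna_refs ncRNA reference sequences per class (rRNA/tRNA/snoRNA).
#' @param mature_length_range mature arm length interval, within \[18,30\] so
#'   planted reads survive the length filter.
#' @param loop_length_range hairpin terminal loop length interval (nt).
#' @param stem_mismatch_rate per-position probability that the star arm
#'   deviates from the exact reverse complement of the mature arm.
#' @param n_reads reads to emit.
#' @param expression_lognormal_mu_sigma log-normal (mu, sigma) for per-gene
#'   expression weights; reproduces heavy-tailed miRNA counts.
#' @param adapter3 3' adapter sequence ligated to every insert (TruSeq
#'   small-RNA adapter prefix by default).
#' @param read_length raw read length; insert + adapter is truncated/padded
#'   to this length.
#' @param error_rate per-base substitution error probability.
#' @param isomir_rates an [isomir_rates()] object.
#' @param background_fraction fraction of reads that are random background
#'   (uniform sequence, 15-35 nt, exercising both sides of the length filter).
#' @param ncrna_fraction fraction of reads sampled as ncRNA reference
#'   fragments.
#' @param ncrna_class_weights mixing weights of rRNA/tRNA/snoRNA within the
#'   ncRNA fraction (rRNA-dominated, as in real libraries).
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(rng_seed = 1L,
                       genome_length = 50000L,
                       n_mirna_genes = 20L,
                       n_conserved_mirnas = NULL,
                       n_ncrna_refs = 5L,
                       mature_length_range = c(20L, 24L),
                       loop_length_range = c(8L, 15L),
                       stem_mismatch_rate = 0.08,
                       n_reads = 50000L,
                       expression_lognormal_mu_sigma = c(2.0, 1.0),
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       read_length = 50L,
                       error_rate = 0.005,
                       isomir_rates = srnakit::isomir_rates(),
                       background_fraction = 0.10,
                       ncrna_fraction = 0.25,
                       ncrna_class_weights = c(rrna = 0.90, trna = 0.08,
                                               snorna = 0.02)) {
  if (is.null(n_conserved_mirnas))
    n_conserved_mirnas <- as.integer(n_mirna_genes) %/% 2L
  cfg <- list(rng_seed = as.integer(rng_seed),
              genome_length = as.integer(genome_length),
              n_mirna_genes = as.integer(n_mirna_genes),
              n_conserved_mirnas = as.integer(n_conserved_mirnas),
              n_ncrna_refs = as.integer(n_ncrna_refs),
              mature_length_range = as.integer(mature_length_range),
              loop_length_range = as.integer(loop_length_range),
              stem_mismatch_rate = stem_mismatch_rate,
              n_reads = as.integer(n_reads),
              expression_lognormal_mu_sigma = expression_lognormal_mu_sigma,
              adapter3 = toupper(adapter3),
              read_length = as.integer(read_length),
              error_rate = error_rate,
              isomir_rates = isomir_rates,
              background_fraction = background_fraction,
              ncrna_fraction = ncrna_fraction,
              ncrna_class_weights = ncrna_class_weights /
                sum(ncrna_class_weights))
  probs <- c(cfg$stem_mismatch_rate, cfg$error_rate, cfg$background_fraction,
             cfg$ncrna_fraction)
  check_that(all(probs >= 0 & probs <= 1), "probabilities must lie in [0,1]")
  check_that(cfg$background_fraction + cfg$ncrna_fraction <= 1,
             "read-class mixture exceeds 1")
  check_that(cfg$mature_length_range[1] >= 18 &&
               cfg$mature_length_range[2] <= 30,
             "mature_length_range must lie within [18,30]")
  check_that(cfg$n_conserved_mirnas <= cfg$n_mirna_genes,
             "n_conserved_mirnas cannot exceed n_mirna_genes")
  check_that(inherits(cfg$isomir_rates, "isomir_rates"),
             "isomir_rates must be built by isomir_rates()")
  structure(cfg, class = "sim_config")
}

# mature arm lengths are drawn with mode 22 nt (Fig-1-like size profile)
mature_length_weights <- function(range) {
  lens <- seq(range[1], range[2])
  w <- stats::dnorm(lens, mean = 22, sd = 1.1)
  w / sum(w)
}

#' Build the toy genome with planted miRNA hairpins
#'
#' Plants `n_mirna_genes` hairpin precursors (mature arm + terminal loop +
#' near-reverse-complement star arm, random arm/strand assignment) at
#' non-overlapping loci in a random background genome, and returns the genome
#' together with a locus manifest.
#'
#' Manifest coordinates are 0-based half-open on the forward genome strand;
#' `mature_seq` and `precursor_seq` are RNA-space, 5'->3' in gene orientation.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (DNA string), `manifest` (data.frame: gene_id,
#'   chrom, strand, pre_start, pre_end, mature_start, mature_end, mature_arm,
#'   mature_seq, precursor_seq, loop_len, conserved).
#' @export
make_genome <- function(config) {
  check_that(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$rng_seed)
  min_gap <- 400L
  lw <- mature_length_weights(config$mature_length_range)
  lens <- seq(config$mature_length_range[1], config$mature_length_range[2])

  genes <- vector("list", config$n_mirna_genes)
  for (i in seq_len(config$n_mirna_genes)) {
    mlen <- sample(lens, 1, prob = lw)
    mature <- random_rna(1, mlen)
    star <- revcomp_rna(mature)
    # star deviates from perfect complementarity at the stem mismatch rate
    sc <- seq_chars(star)
    mm <- which(stats::runif(mlen) < config$stem_mismatch_rate)
    for (p in mm) sc[p] <- sample(setdiff(c("A", "C", "G", "U"), sc[p]), 1)
    star <- paste(sc, collapse = "")
    loop_len <- sample(seq(config$loop_length_range[1],
                           config$loop_length_range[2]), 1)
    loop <- random_rna(1, loop_len)
    arm <- sample(c("5p", "3p"), 1)
    pre <- if (arm == "5p") paste0(mature, loop, star)
           else paste0(star, loop, mature)
    genes[[i]] <- list(mature = mature, star = star, loop_len = loop_len,
                       arm = arm, pre = pre,
                       strand = sample(c("+", "-"), 1))
  }
  pre_lens <- vapply(genes, function(g) nchar(g$pre), integer(1))
  needed <- sum(pre_lens + min_gap) + min_gap
  if (needed > config$genome_length)
    stop("genome too short to place all miRNA loci without overlap",
         call. = FALSE)

  # place loci left to right with randomized spacing
  slack <- config$genome_length - sum(pre_lens) -
    min_gap * (config$n_mirna_genes + 1L)
  extra <- if (config$n_mirna_genes > 0) {
    e <- stats::runif(config$n_mirna_genes + 1L)
    as.integer(floor(e / sum(e) * slack))
  } else slack
  genome_chars <- seq_chars(random_rna(1, config$genome_length,
                                       alphabet = c("A", "C", "G", "T")))
  pos <- 0L
  rows <- vector("list", config$n_mirna_genes)
  for (i in seq_len(config$n_mirna_genes)) {
    pos <- pos + min_gap + extra[i]
    g <- genes[[i]]
    pre_dna <- as_dna(if (g$strand == "+") g$pre else revcomp_rna(g$pre))
    genome_chars[(pos + 1):(pos + pre_lens[i])] <- seq_chars(pre_dna)
    # mature offset within precursor (gene orientation)
    moff <- if (g$arm == "5p") 0L else pre_lens[i] - nchar(g$mature)
    if (g$strand == "+") {
      m_start <- pos + moff
    } else {
      m_start <- pos + pre_lens[i] - moff - nchar(g$mature)
    }
    rows[[i]] <- data.frame(
      gene_id = sprintf("mir-sim-%02d", i), chrom = "chr1",
      strand = g$strand, pre_start = pos, pre_end = pos + pre_lens[i],
      mature_start = m_start, mature_end = m_start + nchar(g$mature),
      mature_arm = g$arm, mature_seq = g$mature, precursor_seq = g$pre,
      loop_len = g$loop_len,
      conserved = i <= config$n_conserved_mirnas,
      stringsAsFactors = FALSE)
    pos <- pos + pre_lens[i]
  }
  list(genome = paste(genome_chars, collapse = ""),
       manifest = do.call(rbind, rows))
}

#' Generate ncRNA reference sets
#'
#' Random rRNA/tRNA/snoRNA reference sequences (not embedded in the genome);
#' library reads of these classes are sampled as internal fragments.
#'
#' @param config a [sim_config()].
#' @return named list of named RNA character vectors: `rrna`, `trna`, `snorna`.
#' @export
make_ncrna_refs <- function(config) {
  lens <- c(rrna = 120L, trna = 75L, snorna = 100L)
  out <- lapply(names(lens), function(cl) {
    s <- random_rna(config$n_ncrna_refs, lens[[cl]])
    names(s) <- sprintf("%s-%d", cl, seq_along(s))
    s
  })
  names(out) <- names(lens)
  out
}

#' Apply one isomiR edit to a canonical mature sequence
#'
#' Draws a variant class from the rate mixture and applies it. Templated
#' extensions copy bases from the genomic/precursor flank; non-templated 3'
#' additions append A or U chosen not to match the flank base, so the edit is
#' identifiable. The returned record labels the exact edit (ground truth).
#'
#' @param canonical canonical mature sequence (RNA).
#' @param context precursor-with-flanks sequence (RNA) containing `canonical`.
#' @param ctx_start 1-based start of `canonical` within `context`; if missing
#'   it is located by exact match.
#' @param rates an [isomir_rates()].
#' @return list: `seq` (variant), `class` (canonical/iso5/iso3/internal),
#'   `offset5`, `offset3` (signed nt, negative = trimmed), `sub_positions`
#'   (1-based in the variant), `templated` (NA unless an extension was made),
#'   `generator_branch`.
#' @export
apply_isomir <- function(canonical, context, ctx_start = NULL,
                         rates = isomir_rates()) {
  if (is.null(ctx_start)) {
    ctx_start <- as.integer(regexpr(canonical, context, fixed = TRUE))
    check_that(ctx_start > 0, "canonical not found in context")
  }
  len <- nchar(canonical)
  ctx_end <- ctx_start + len - 1L
  check_that(ctx_start > 8 && nchar(context) - ctx_end >= 8,
             "context must flank the canonical sequence by >= 8 nt")
  branch <- sample(names(rates$p), 1, prob = rates$p)
  res <- list(seq = canonical, class = "canonical", offset5 = 0L,
              offset3 = 0L, sub_positions = integer(0), templated = NA,
              generator_branch = branch)
  geom_len <- function(kmax) {
    if (kmax < 1L) return(0L)
    min(1L + stats::rgeom(1, rates$trim_step), kmax)
  }
  kmax_trim <- min(rates$max_offset, len - 18L)
  kmax_ext3 <- min(rates$max_offset, 30L - len,
                   nchar(context) - ctx_end)
  switch(branch,
    canonical = NULL,
    trim3 = {
      k <- geom_len(kmax_trim)
      if (k > 0L) {
        res$seq <- substr(canonical, 1L, len - k)
        res$class <- "iso3"; res$offset3 <- -k
      }
    },
    trim5 = {
      k <- geom_len(kmax_trim)
      if (k > 0L) {
        res$seq <- substr(canonical, 1L + k, len)
        res$class <- "iso5"; res$offset5 <- -k
      }
    },
    ext3_templated = {
      k <- geom_len(kmax_ext3)
      if (k > 0L) {
        added <- substr(context, ctx_end + 1L, ctx_end + k)
        res$seq <- paste0(canonical, added)
        res$class <- "iso3"; res$offset3 <- k; res$templated <- TRUE
      }
    },
    add3_nontemplated = {
      if (len < 30L) {
        flank1 <- substr(context, ctx_end + 1L, ctx_end + 1L)
        choice <- setdiff(c("A", "U"), flank1)
        base <- if (length(choice) == 1L) choice
                else sample(names(rates$add3_weights), 1,
                            prob = rates$add3_weights)
        res$seq <- paste0(canonical, base)
        res$class <- "iso3"; res$offset3 <- 1L; res$templated <- FALSE
      }
    },
    shift5 = {
      dir <- sample(c(-1L, 1L), 1)
      if (dir == 1L && len < 30L) {
        added <- substr(context, ctx_start - 1L, ctx_start - 1L)
        res$seq <- paste0(added, canonical)
        res$class <- "iso5"; res$offset5 <- 1L; res$templated <- TRUE
      } else if (len > 18L) {
        res$seq <- substr(canonical, 2L, len)
        res$class <- "iso5"; res$offset5 <- -1L
      }
    },
    substitution = {
      p <- sample.int(len, 1)
      ch <- seq_chars(canonical)
      ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1)
      res$seq <- paste(ch, collapse = "")
      res$class <- "internal"; res$sub_positions <- p
    })
  res
}

#' Simulate the synthetic small-RNA library
#'
#' Builds the genome and references, draws per-gene log-normal expression,
#' then emits `n_reads` reads: each is an (optionally isomiR-edited) source
#' insert plus the 3' adapter, padded with random bases and truncated to the
#' read length, with per-base errors and Phred+33 qualities (correct bases
#' Q30-40, error bases low-Q). A ground-truth row is recorded per read.
#'
#' @param config a [sim_config()].
#' @param fastq_path optional path; when given the FASTQ is written there.
#' @return list: `fastq` (character vector of FASTQ lines), `truth`
#'   (data.frame, one row per read), `genome`, `manifest`, `ncrna_refs`,
#'   `mature_refs` (named RNA vector of the conserved genes' matures),
#'   `expression` (per-gene weights), `config`.
#' @export
simulate_library <- function(config, fastq_path = NULL) {
  gm <- make_genome(config)
  ncrna <- make_ncrna_refs(config)
  manifest <- gm$manifest
  set.seed((config$rng_seed + 7919L) %% .Machine$integer.max)

  mu <- config$expression_lognormal_mu_sigma[1]
  sigma <- config$expression_lognormal_mu_sigma[2]
  expr <- stats::rlnorm(nrow(manifest), meanlog = mu, sdlog = sigma)
  names(expr) <- manifest$gene_id

  # precursor context with 10-nt genomic flanks, gene orientation
  ctx <- character(nrow(manifest))
  ctx_mstart <- integer(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    s <- manifest$pre_start[i] - 10L
    e <- manifest$pre_end[i] + 10L
    sub <- substr(gm$genome, s + 1L, e)
    if (manifest$strand[i] == "+") {
      ctx[i] <- as_rna(sub)
      ctx_mstart[i] <- manifest$mature_start[i] - s + 1L
    } else {
      ctx[i] <- revcomp_rna(as_rna(sub))
      ctx_mstart[i] <- e - manifest$mature_end[i] + 1L
    }
  }

  n <- config$n_reads
  u <- stats::runif(n)
  src_class <- ifelse(u < config$background_fraction, "background",
               ifelse(u < config$background_fraction + config$ncrna_fraction,
                      "ncrna", "mirna"))
  adapter <- config$adapter3
  rl <- config$read_length

  ids <- sprintf("read%06d", seq_len(n))
  insert <- character(n)
  source <- character(n)
  iso_class <- rep("none", n)
  off5 <- integer(n); off3 <- integer(n)
  subs <- character(n); templ <- rep(NA, n)

  nc_classes <- names(config$ncrna_class_weights)
  for (r in seq_len(n)) {
    cl <- src_class[r]
    if (cl == "background") {
      insert[r] <- random_rna(1, sample(15:35, 1))
      source[r] <- "background"
    } else if (cl == "ncrna") {
      k <- sample(nc_classes, 1, prob = config$ncrna_class_weights)
      ref <- ncrna[[k]][sample.int(length(ncrna[[k]]), 1)]
      flen <- sample(18:30, 1, prob = stats::dnorm(18:30, 22, 3))
      st <- sample.int(nchar(ref) - flen + 1L, 1)
      insert[r] <- substr(ref, st, st + flen - 1L)
      source[r] <- k
    } else {
      gi <- sample.int(nrow(manifest), 1, prob = expr)
      v <- apply_isomir(manifest$mature_seq[gi], ctx[gi], ctx_mstart[gi],
                        config$isomir_rates)
      insert[r] <- v$seq
      source[r] <- manifest$gene_id[gi]
      iso_class[r] <- if (v$class == "canonical") "canonical" else v$class
      off5[r] <- v$offset5; off3[r] <- v$offset3
      subs[r] <- paste(v$sub_positions, collapse = ",")
      templ[r] <- v$templated
    }
  }

  # assemble raw reads: insert + adapter + random fill, truncated
  raw <- paste0(as_dna(insert), adapter)
  short <- nchar(raw) < rl
  if (any(short)) {
    fill <- random_rna(sum(short), rl - nchar(raw)[short],
                       alphabet = c("A", "C", "G", "T"))
    raw[short] <- paste0(raw[short], fill)
  }
  raw <- substr(raw, 1L, rl)

  # per-base substitution errors with low quality at error positions
  seqs <- character(n); quals <- character(n)
  for (r in seq_len(n)) {
    ch <- seq_chars(raw[r])
    L <- length(ch)
    q <- sample(30:40, L, replace = TRUE)
    if (config$error_rate > 0) {
      err <- which(stats::runif(L) < config$error_rate)
      for (p in err) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        q[p] <- sample(3:15, 1)
      }
    }
    seqs[r] <- paste(ch, collapse = "")
    quals[r] <- phred_encode(q)
  }

  truth <- data.frame(read_id = ids, source = source,
                      isomir_class = iso_class, offset5 = off5,
                      offset3 = off3, sub_positions = subs,
                      templated = templ, insert_seq = insert,
                      insert_len = nchar(insert), stringsAsFactors = FALSE)

  fastq <- as.vector(rbind(paste0("@", ids), seqs, "+", quals))
  if (!is.null(fastq_path)) writeLines(fastq, fastq_path)

  mature_refs <- manifest$mature_seq[manifest$conserved]
  names(mature_refs) <- manifest$gene_id[manifest$conserved]

  list(fastq = fastq, truth = truth, genome = gm$genome,
       manifest = manifest, ncrna_refs = ncrna, mature_refs = mature_refs,
       expression = expr, config = config)
}

#' Write the locus manifest as GFF3
#'
#' Converts the 0-based half-open manifest coordinates to the 1-based
#' inclusive GFF3 convention; one `pre_miRNA` and one `miRNA` feature per
#' planted gene.
#'
#' @param manifest manifest data.frame from [make_genome()].
#' @param path output file.
#' @return invisibly, the GFF3 lines.
#' @export
write_manifest_gff3 <- function(manifest, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    lines <- c(lines,
      sprintf("%s\tsrnakit\tpre_miRNA\t%d\t%d\t.\t%s\t.\tID=%s_pre",
              m$chrom, m$pre_start + 1L, m$pre_end, m$strand, m$gene_id),
      sprintf("%s\tsrnakit\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s_pre",
              m$chrom, m$mature_start + 1L, m$mature_end, m$strand,
              m$gene_id, m$gene_id))
  }
  writeLines(lines, path)
  invisible(lines)
}
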