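mk_tags <- function(seqs, counts) {
  data.frame(tag_id = paste0("tag", seq_along(seqs)), sequence = seqs,
             count = as.integer(counts), stringsAsFactors = FALSE)
}

test_that("overlapping same-strand alignments merge; strands stay apart", {
  tags <- mk_tags(c("ACGUACGUACGUACGUACGUAC", "GGGGACGUACGUACGUACGUAC"),
                  c(5, 3))
  aln <- data.frame(tag_id = c("tag1", "tag2"), chrom = "chr1",
                    start = c(100L, 107L), end = c(122L, 129L),
                    strand = "+", stringsAsFactors = FALSE)
  cl <- cluster_tags(aln, tags)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$start, 100L)
  expect_identical(cl$end, 129L)
  expect_identical(cl$anchor_tag, "tag1")   # highest count anchors

  aln2 <- aln; aln2$strand <- c("+", "-")
  expect_identical(nrow(cluster_tags(aln2, tags)), 2L)
})

test_that("alignments separated by more than the merge gap split", {
  tags <- mk_tags(c("A", "B"), c(1, 1))
  aln <- data.frame(tag_id = c("tag1", "tag2"), chrom = "chr1",
                    start = c(100L, 140L), end = c(122L, 162L),
                    strand = "+", stringsAsFactors = FALSE)
  expect_identical(nrow(cluster_tags(aln, tags, merge_gap = 10L)), 2L)
  expect_identical(nrow(cluster_tags(aln, tags, merge_gap = 20L)), 1L)
})

test_that("window excision arithmetic and boundary truncation", {
  genome <- paste(rep("ACGT", 500), collapse = "")  # 2000 nt
  cl <- data.frame(chrom = "chr1", start = 1000L, end = 1022L,
                   strand = "+", anchor_tag = "tag1",
                   anchor_start = 1000L, anchor_end = 1022L,
                   stringsAsFactors = FALSE)
  w <- excise_windows(genome, cl, flank = 150L)
  expect_identical(w[[1]]$g_start, 980L)
  expect_identical(w[[1]]$g_end, 1172L)
  expect_identical(w[[1]]$anchor_in_window, c(21L, 22L + 20L))
  expect_identical(w[[2]]$g_start, 850L)
  expect_identical(w[[2]]$g_end, 1042L)
  expect_false(w[[1]]$truncated)

  cl$start <- cl$anchor_start <- 5L; cl$end <- cl$anchor_end <- 27L
  wt <- excise_windows(genome, cl, flank = 150L)
  expect_true(wt[[1]]$truncated)
  expect_identical(wt[[1]]$g_start, 0L)
})

test_that("minus-strand windows present the mature 5'->3'", {
  set.seed(81)
  mature <- random_rna_str(22)
  genome <- as_dna(paste0(random_rna_str(300), revcomp_rna(mature),
                          random_rna_str(300)))
  cl <- data.frame(chrom = "chr1", start = 300L, end = 322L, strand = "-",
                   anchor_tag = "tag1", anchor_start = 300L,
                   anchor_end = 322L, stringsAsFactors = FALSE)
  w <- excise_windows(genome, cl, flank = 50L)
  for (k in 1:2) {
    a <- w[[k]]$anchor_in_window
    expect_identical(substr(w[[k]]$seq, a[1], a[2]), mature)
  }
})

# a clean constructed hairpin: mature 5p arm, 10-nt loop, perfect star
perfect_hairpin_window <- function(flank = 120) {
  set.seed(83)
  mature <- "UGAGGUAGUAGGUUGUAUAGUU"
  loop <- "ACAUACAUAC"
  pre <- paste0(mature, loop, revcomp_rna(mature))
  wseq <- paste0(pre, random_rna_str(flank))
  list(seq = wseq, g_start = 0L, g_end = nchar(wseq), strand = "+",
       anchor_in_window = c(1L, nchar(mature)), truncated = FALSE,
       arm_hypothesis = "5p")
}

test_that("a planted perfect hairpin with three distinct reads is accepted", {
  w <- perfect_hairpin_window()
  ev <- evaluate_hairpin(w, support_starts = c(1L, 2L, 33L))
  expect_true(ev$accepted)
  expect_true(all(ev$flags))
  expect_identical(ev$mature_arm, "5p")
  expect_gte(ev$pairing_fraction, 0.9)
  # the mature sequence is contained in the reported precursor
  expect_true(grepl(substr(w$seq, 1, 22), ev$precursor, fixed = TRUE))
})

test_that("the same hairpin with a single supporting tag is rejected", {
  w <- perfect_hairpin_window()
  ev <- evaluate_hairpin(w, support_starts = 1L)
  expect_false(ev$accepted)
  expect_false(ev$flags[["support_ok"]])
  expect_true(ev$flags[["unbranched"]])
})

test_that("support outside the mature/star neighborhoods does not count", {
  w <- perfect_hairpin_window()
  ev <- evaluate_hairpin(w, support_starts = c(1L, 15L))
  expect_false(ev$flags[["support_ok"]])
})

test_that("candidate naming orders by count and suffixes shared matures", {
  cand <- data.frame(
    chrom = "chr1", start = c(10L, 200L, 400L, 600L),
    mature_seq = c("AAAA", "CCCC", "AAAA", "GGGG"),
    total_count = c(50, 200, 80, 10), stringsAsFactors = FALSE)
  named <- name_candidates(cand)
  expect_identical(named$name,
                   c("Novel-1", "Novel-2a", "Novel-2b", "Novel-3"))
  # permutation invariance
  named2 <- name_candidates(cand[c(3, 1, 4, 2), ])
  expect_identical(named2$name, named$name)
  expect_identical(named2$total_count, named$total_count)
})

test_that("discovery reports planted novel loci on a small library", {
  sim <- tiny_sim(seed = 85, n_reads = 6000)
  pre <- preprocess_fastq(sim$fastq, sim$config$adapter3)
  ann <- classify_tags(pre$tags, sim$genome,
                       c(list(mature = sim$mature_refs), sim$ncrna_refs))
  nov <- find_novel_mirnas(pre$tags, ann$alignments, sim$genome)
  expect_gt(nrow(nov), 0)
  # every reported mature is a substring of its precursor
  for (i in seq_len(nrow(nov)))
    expect_true(grepl(nov$mature_seq[i], nov$precursor_seq[i], fixed = TRUE))
  # all reported candidates carry >= 2 distinct supporting tags
  expect_true(all(nov$n_support_tags >= 2))
  # at least half of the well-expressed planted novel loci are reported
  man <- sim$manifest[!sim$manifest$conserved, ]
  rec <- vapply(seq_len(nrow(man)), function(i) {
    m <- man[i, ]
    any(nov$strand == m$strand & nov$start < m$pre_end &
        nov$end > m$pre_start)
  }, logical(1))
  expect_gte(mean(rec), 0.5)
})
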