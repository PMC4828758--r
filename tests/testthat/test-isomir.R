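test_that("seed extraction returns positions 2-8", {
  expect_identical(extract_seed("UUGACUCUAGUCUGGCACUGUGAAGA"), "UGACUCU")
  expect_identical(extract_seed("AUCAUUUUUGUGACUAUGCAACU"), "UCAUUUU")
  expect_identical(extract_seed("AAAAAAAA"), "AAAAAAA")
  expect_error(extract_seed("AAAAAAA"), "length >= 8")
})

canonical <- "UGAGGUAGUAGGUUGUAUAGUU"
context <- paste0("GCAUCGAUCG", canonical, "CGUAGCAUGG")

test_that("alignment to the canonical handles ends and substitutions", {
  a <- align_to_canonical(canonical, canonical)
  expect_identical(c(a$offset5, a$offset3), c(0L, 0L))
  expect_identical(nrow(a$substitutions), 0L)

  tr <- align_to_canonical(substr(canonical, 1, 20), canonical)
  expect_identical(c(tr$offset5, tr$offset3), c(0L, -2L))

  tc <- strsplit(canonical, "")[[1]]
  tc[5] <- "C"  # G -> C inside the seed
  sub <- align_to_canonical(paste(tc, collapse = ""), canonical)
  expect_identical(c(sub$offset5, sub$offset3), c(0L, 0L))
  expect_identical(sub$substitutions$pos_canonical, 5L)
  expect_true(sub$substitutions$in_seed)

  expect_error(align_to_canonical(random_rna_str(22), canonical),
               "cannot be assigned")
})

test_that("alignment agrees with the exhaustive offset-pair oracle", {
  set.seed(91)
  rates <- isomir_rates()
  for (i in 1:200) {
    v <- apply_isomir(canonical, context, rates = rates)
    a <- align_to_canonical(v$seq, canonical)
    o <- oracle_align_canonical(v$seq, canonical)
    expect_identical(c(a$offset5, a$offset3), c(o$o5, o$o3))
    expect_identical(nrow(a$substitutions), as.integer(o$mm))
  }
})

test_that("classification recovers every generated variant class exactly", {
  set.seed(92)
  rates <- isomir_rates(p_canonical = 0.2, p_trim3 = 0.2, p_trim5 = 0.15,
                        p_ext3_templated = 0.15, p_add3_nontemplated = 0.1,
                        p_shift5 = 0.1, p_substitution = 0.1)
  for (i in 1:300) {
    v <- apply_isomir(canonical, context, rates = rates)
    rec <- classify_isomir(v$seq, canonical, context)
    expect_identical(rec$class, ifelse(v$class == "canonical", "canonical",
                                       v$class), info = v$generator_branch)
    expect_identical(rec$offset5, v$offset5)
    expect_identical(rec$offset3, v$offset3)
    if (!is.na(v$templated)) expect_identical(rec$templated, v$templated)
  }
})

test_that("classification is a fixed point on the canonical sequence", {
  rec <- classify_isomir(canonical, canonical, context)
  expect_identical(rec$class, "canonical")
  expect_identical(rec$subtype5, "none")
  expect_identical(rec$subtype3, "none")
})

test_that("a templated 5' extension shifts the seed frame as iso5", {
  ext <- paste0(substr(context, 10, 10), canonical)
  rec <- classify_isomir(ext, canonical, context)
  expect_identical(rec$class, "iso5")
  expect_identical(rec$subtype5, "ext_templated")
  expect_false(identical(extract_seed(ext), extract_seed(canonical)))
})

test_that("non-templated 3' additions are typed by the added nucleotide", {
  flank1 <- substr(context, 33, 33)  # base after the canonical
  base <- setdiff(c("A", "U"), flank1)[1]
  rec <- classify_isomir(paste0(canonical, base), canonical, context)
  expect_identical(rec$class, "iso3")
  expect_identical(rec$subtype3, "add_nontemplated")
  expect_identical(rec$added3, base)
  expect_false(rec$templated)
})

test_that("edits at both ends are classed as mixed", {
  v <- paste0(substr(canonical, 2, nchar(canonical) - 1))  # trim both ends
  rec <- classify_isomir(v, canonical, context)
  expect_identical(rec$class, "mixed")
})

test_that("summaries weight by reads, normalize, and are order-invariant", {
  recs <- data.frame(
    mirna_id = c("mirA-5p", "mirA-5p", "mirA-3p", "mirB"),
    tag_id = paste0("t", 1:4), count = c(70L, 20L, 9L, 1L),
    class = c("canonical", "iso3", "iso5", "internal"),
    subtype5 = c("none", "none", "trim", "none"),
    subtype3 = c("none", "trim", "none", "none"),
    added3 = NA_character_, offset5 = c(0L, 0L, -1L, 0L),
    offset3 = c(0L, -2L, 0L, 0L), templated = NA,
    n_sub = c(0L, 0L, 0L, 1L), n_sub_seed = 0L,
    sub_positions = c("", "", "", "12"), stringsAsFactors = FALSE)
  s <- summarize_isomirs(recs)
  expect_equal(sum(s$class_fractions), 1)
  expect_equal(s$class_fractions[["canonical"]], 0.70)
  expect_equal(s$class_fractions[["iso3"]], 0.20)
  expect_equal(s$iso3_trim_share, 1.0)
  expect_equal(sum(s$noncanonical_fractions), 1)

  s2 <- summarize_isomirs(recs[c(3, 1, 4, 2), ])
  expect_equal(s$class_fractions, s2$class_fractions)

  # splitting a tag's count across duplicate records changes nothing
  split <- rbind(recs, recs[2, ])
  split$count[c(2, 5)] <- c(12L, 8L)
  s3 <- summarize_isomirs(split)
  expect_equal(s$class_fractions, s3$class_fractions)

  # per-arm distinct isomiR counts
  per <- s$per_mirna
  expect_identical(per$n_isomirs[per$mirna_id == "mirA-5p"], 2L)
  expect_identical(per$arm[per$mirna_id == "mirA-3p"], "3p")
})

test_that("an all-canonical record set has zero isomiR fractions", {
  recs <- data.frame(mirna_id = "m", tag_id = "t1", count = 10L,
                     class = "canonical", subtype5 = "none",
                     subtype3 = "none", added3 = NA_character_,
                     offset5 = 0L, offset3 = 0L, templated = NA,
                     n_sub = 0L, n_sub_seed = 0L, sub_positions = "",
                     stringsAsFactors = FALSE)
  s <- summarize_isomirs(recs)
  expect_identical(s$class_fractions[["canonical"]], 1)
  expect_identical(sum(s$class_fractions[c("iso5", "iso3", "internal",
                                           "mixed")]), 0)
})
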