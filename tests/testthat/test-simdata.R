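test_that("zero stem mismatch rate plants an exact reverse-complement star", {
  cfg <- sim_config(rng_seed = 3, n_mirna_genes = 1, stem_mismatch_rate = 0,
                    genome_length = 5000)
  gm <- make_genome(cfg)
  m <- gm$manifest[1, ]
  pre <- m$precursor_seq
  mlen <- nchar(m$mature_seq)
  if (m$mature_arm == "5p") {
    star <- substr(pre, nchar(pre) - mlen + 1L, nchar(pre))
    expect_identical(substr(pre, 1, mlen), m$mature_seq)
  } else {
    star <- substr(pre, 1, mlen)
    expect_identical(substr(pre, nchar(pre) - mlen + 1L, nchar(pre)),
                     m$mature_seq)
  }
  expect_identical(star, revcomp_rna(m$mature_seq))
})

test_that("genome construction is deterministic under a fixed seed", {
  cfg <- sim_config(rng_seed = 9, genome_length = 20000, n_mirna_genes = 6)
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$manifest, g2$manifest)
})

test_that("a too-short genome raises a sizing error", {
  expect_error(make_genome(sim_config(genome_length = 2000,
                                      n_mirna_genes = 20)),
               "too short")
})

test_that("planted precursors fold into hairpins that pass evaluation", {
  # zero stem mismatches: the planted duplex is the unambiguous fold
  cfg <- sim_config(rng_seed = 21, n_mirna_genes = 6, genome_length = 20000,
                    stem_mismatch_rate = 0)
  gm <- make_genome(cfg)
  for (i in seq_len(nrow(gm$manifest))) {
    m <- gm$manifest[i, ]
    # present the planted locus the way discovery would see it
    window <- list(seq = m$precursor_seq,
                   anchor_in_window = NULL, strand = "+",
                   g_start = 0L, g_end = nchar(m$precursor_seq),
                   arm_hypothesis = m$mature_arm, truncated = FALSE)
    mlen <- nchar(m$mature_seq)
    mi <- if (m$mature_arm == "5p") c(1L, mlen)
          else c(nchar(m$precursor_seq) - mlen + 1L, nchar(m$precursor_seq))
    ev <- evaluate_hairpin(window, mature_interval = mi,
                           support_starts = c(mi[1], mi[1] + 1L))
    expect_true(all(ev$flags[c("unbranched", "mature_in_one_arm",
                               "pairing_fraction_ok")]),
                info = paste("gene", m$gene_id))
  }
})

test_that("apply_isomir with a degenerate mixture returns the canonical", {
  rates <- isomir_rates(p_canonical = 1, p_trim3 = 0, p_trim5 = 0,
                        p_ext3_templated = 0, p_add3_nontemplated = 0,
                        p_shift5 = 0, p_substitution = 0)
  canonical <- "UGAGGUAGUAGGUUGUAUAGUU"
  ctx <- paste0("ACGUACGUAC", canonical, "CAGUCAGUCA")
  set.seed(1)
  v <- apply_isomir(canonical, ctx, rates = rates)
  expect_identical(v$seq, canonical)
  expect_identical(v$class, "canonical")
  expect_identical(c(v$offset5, v$offset3), c(0L, 0L))
})

test_that("forced 3' trimming removes terminal bases and records the offset", {
  rates <- isomir_rates(p_canonical = 0, p_trim3 = 1, p_trim5 = 0,
                        p_ext3_templated = 0, p_add3_nontemplated = 0,
                        p_shift5 = 0, p_substitution = 0)
  canonical <- "UGAGGUAGUAGGUUGUAUAGUU"
  ctx <- paste0("ACGUACGUAC", canonical, "CAGUCAGUCA")
  set.seed(4)
  for (i in 1:20) {
    v <- apply_isomir(canonical, ctx, rates = rates)
    k <- -v$offset3
    expect_gte(k, 1L)
    expect_identical(v$seq, substr(canonical, 1, nchar(canonical) - k))
    expect_identical(v$class, "iso3")
  }
})

test_that("isomiR class draws follow the configured mixture", {
  rates <- isomir_rates(p_canonical = 0.6, p_trim3 = 0.3, p_trim5 = 0,
                        p_ext3_templated = 0, p_add3_nontemplated = 0,
                        p_shift5 = 0.05, p_substitution = 0.05)
  canonical <- "UGAGGUAGUAGGUUGUAUAGUU"
  ctx <- paste0("ACGUACGUAC", canonical, "CAGUCAGUCA")
  set.seed(11)
  n <- 10000
  cls <- vapply(seq_len(n), function(i)
    apply_isomir(canonical, ctx, rates = rates)$class, character(1))
  emp <- c(canonical = mean(cls == "canonical"),
           iso3 = mean(cls == "iso3"),
           iso5 = mean(cls == "iso5"),
           internal = mean(cls == "internal"))
  want <- c(canonical = 0.6, iso3 = 0.3, iso5 = 0.05, internal = 0.05)
  se <- sqrt(want * (1 - want) / n)
  expect_true(all(abs(emp - want) <= 3 * se))
})

test_that("a noise-free canonical-only library emits exactly planted matures", {
  rates <- isomir_rates(p_canonical = 1, p_trim3 = 0, p_trim5 = 0,
                        p_ext3_templated = 0, p_add3_nontemplated = 0,
                        p_shift5 = 0, p_substitution = 0)
  sim <- tiny_sim(seed = 5, n_reads = 500, error_rate = 0,
                  background_fraction = 0, ncrna_fraction = 0,
                  isomir_rates = rates)
  expect_true(all(sim$truth$insert_seq %in% sim$manifest$mature_seq))
})

test_that("simulation is byte-identical under a fixed seed and conserves reads", {
  s1 <- tiny_sim(seed = 13, n_reads = 400)
  s2 <- tiny_sim(seed = 13, n_reads = 400)
  expect_identical(s1$fastq, s2$fastq)
  expect_identical(s1$truth, s2$truth)
  expect_identical(length(s1$fastq), 4L * 400L)
  expect_identical(nrow(s1$truth), 400L)
})

test_that("insert lengths are 18-30 dominated with mode 22", {
  sim <- tiny_sim(seed = 17, n_reads = 8000)
  nb <- sim$truth[sim$truth$source != "background", ]
  expect_gte(mean(nb$insert_len >= 18 & nb$insert_len <= 30), 0.95)
  tab <- table(nb$insert_len)
  expect_identical(names(which.max(tab)), "22")
})

test_that("manifest GFF3 uses 1-based inclusive coordinates", {
  cfg <- sim_config(rng_seed = 3, n_mirna_genes = 2, genome_length = 8000)
  gm <- make_genome(cfg)
  path <- tempfile(fileext = ".gff3")
  write_manifest_gff3(gm$manifest, path)
  lines <- readLines(path)
  expect_identical(lines[1], "##gff-version 3")
  f <- strsplit(lines[2], "\t")[[1]]
  expect_identical(as.integer(f[4]), gm$manifest$pre_start[1] + 1L)
  expect_identical(as.integer(f[5]), gm$manifest$pre_end[1])
})
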