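test_that("genome mapping finds planted tags at threshold boundaries", {
  set.seed(51)
  genome <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  tag <- as_rna(substr(genome, 1001, 1022))
  hit <- map_to_genome(tag, genome, max_mm = 1)
  expect_true(any(hit$start == 1000 & hit$strand == "+" &
                  hit$n_mismatches == 0))

  tc <- strsplit(tag, "")[[1]]
  tc[5] <- setdiff(c("A", "C", "G", "U"), tc[5])[1]
  one_mm <- paste(tc, collapse = "")
  h1 <- map_to_genome(one_mm, genome, max_mm = 1)
  expect_true(any(h1$start == 1000 & h1$n_mismatches == 1))

  tc[9] <- setdiff(c("A", "C", "G", "U"), tc[9])[1]
  two_mm <- paste(tc, collapse = "")
  h2 <- map_to_genome(two_mm, genome, max_mm = 1)
  expect_false(any(h2$start == 1000))
})

test_that("minus-strand hits are found at the reverse complement locus", {
  set.seed(52)
  genome <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  tag <- revcomp_rna(as_rna(substr(genome, 501, 522)))
  hit <- map_to_genome(tag, genome, max_mm = 0)
  expect_true(any(hit$start == 500 & hit$strand == "-"))
})

test_that("genome mapping equals the exhaustive-scan oracle", {
  set.seed(53)
  genome <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  for (i in 1:60) {
    if (i <= 30) {
      tag <- random_rna_str(sample(18:25, 1))
    } else {
      # planted with 0-2 mutations so hits actually occur
      st <- sample(1:2970, 1)
      tc <- strsplit(as_rna(substr(genome, st, st + 21)), "")[[1]]
      for (p in sample(22, sample(0:2, 1)))
        tc[p] <- sample(setdiff(c("A", "C", "G", "U"), tc[p]), 1)
      tag <- paste(tc, collapse = "")
    }
    got <- map_to_genome(tag, genome, max_mm = 1)
    want <- oracle_genome_scan(tag, genome, max_mm = 1)
    key <- function(d) sort(paste(d$start, d$strand, d$n_mismatches))
    expect_identical(key(got), key(want))
  }
})

test_that("reference containment matches windows and honors tie-breaks", {
  refs <- c(rrna1 = random_rna_str(100), rrna2 = random_rna_str(100))
  tag <- substr(refs[["rrna1"]], 40, 59)
  h <- match_reference_set(tag, refs, max_mm = 1)
  expect_identical(h$reference_id, "rrna1")
  expect_identical(h$n_mismatches, 0L)
  expect_identical(h$offset, 39L)
  expect_null(match_reference_set(paste(rep("A", 25), collapse = ""),
                                  refs, max_mm = 1))
})

test_that("reference containment equals the all-offsets oracle", {
  set.seed(54)
  for (i in 1:60) {
    refs <- setNames(vapply(1:4, function(k) random_rna_str(80),
                            character(1)), paste0("ref", 1:4))
    if (i %% 2 == 0) {
      ri <- sample(4, 1); off <- sample(1:60, 1)
      tc <- strsplit(substr(refs[[ri]], off, off + 19), "")[[1]]
      for (p in sample(20, sample(0:1, 1)))
        tc[p] <- sample(setdiff(c("A", "C", "G", "U"), tc[p]), 1)
      tag <- paste(tc, collapse = "")
    } else tag <- random_rna_str(20)
    got <- match_reference_set(tag, refs, max_mm = 1)
    want <- oracle_ref_match(tag, refs, max_mm = 1)
    if (is.null(want)) expect_null(got)
    else {
      expect_identical(got$reference_id, want$reference_id)
      expect_identical(got$n_mismatches, want$n_mismatches)
    }
  }
})

test_that("conserved matching admits terminal isomiRs within bounds", {
  refs <- c(mirA = "UGAGGUAGUAGGUUGUAUAGUU", mirB = random_rna_str(22))
  exact <- match_conserved_mirna(refs[["mirA"]], refs)
  expect_identical(exact$reference_id, "mirA")
  expect_identical(exact$n_mismatches, 0L)
  expect_identical(c(exact$offset5, exact$offset3), c(0L, 0L))

  trimmed <- match_conserved_mirna(substr(refs[["mirA"]], 1, 20), refs)
  expect_identical(trimmed$reference_id, "mirA")
  expect_identical(trimmed$offset3, -2L)

  tc <- strsplit(refs[["mirA"]], "")[[1]]
  for (p in c(3, 10, 15))
    tc[p] <- setdiff(c("A", "C", "G", "U"), tc[p])[1]
  expect_null(match_conserved_mirna(paste(tc, collapse = ""), refs,
                                    max_mm = 2))
})

test_that("conserved matching requires the overlap to cover the seed", {
  refs <- c(mirA = "UGAGGUAGUAGGUUGUAUAGUU")
  # a tag equal to the last 14 nt would need a 5' offset of 8
  expect_null(match_conserved_mirna(substr(refs[["mirA"]], 9, 22), refs))
})

test_that("category precedence puts conserved miRNA above ncRNA classes", {
  mature <- "UGAGGUAGUAGGUUGUAUAGUU"
  tc <- strsplit(mature, "")[[1]]
  tc[12] <- setdiff(c("A", "C", "G", "U"), tc[12])[1]
  tag_1mm <- paste(tc, collapse = "")  # 1 mm to the mature
  refs <- list(mature = c(mirA = mature),
               rrna = c(rrna1 = paste0(random_rna_str(30), tag_1mm,
                                       random_rna_str(30))))
  genome <- as_dna(paste0(random_rna_str(500), mature, random_rna_str(500)))
  tags <- collapse(tag_1mm)
  res <- classify_tags(tags, genome, refs)
  expect_identical(res$records$category, "conserved_mirna")
})

test_that("overlapping reference names across sets raise a config error", {
  refs <- list(mature = c(x = "UGAGGUAGUAGGUUGUAUAGUU"),
               rrna = c(x = random_rna_str(50)))
  expect_error(classify_tags(collapse("ACGUACGUACGUACGUACGU"),
                             "ACGT", refs), "overlap")
})

test_that("noise-free classification reproduces the truth table sources", {
  rates <- isomir_rates(p_canonical = 1, p_trim3 = 0, p_trim5 = 0,
                        p_ext3_templated = 0, p_add3_nontemplated = 0,
                        p_shift5 = 0, p_substitution = 0)
  sim <- tiny_sim(seed = 61, n_reads = 1500, error_rate = 0,
                  isomir_rates = rates)
  pre <- preprocess_fastq(sim$fastq, sim$config$adapter3)
  ann <- classify_tags(pre$tags, sim$genome,
                       c(list(mature = sim$mature_refs), sim$ncrna_refs))
  # expected category per tag from the truth table
  truth_src <- tapply(sim$truth$source, as_rna(sim$truth$insert_seq),
                      function(x) x[1])
  conserved_genes <- sim$manifest$gene_id[sim$manifest$conserved]
  novel_genes <- sim$manifest$gene_id[!sim$manifest$conserved]
  for (i in seq_len(nrow(pre$tags))) {
    src <- truth_src[[pre$tags$sequence[i]]]
    cat_got <- ann$records$category[i]
    if (src %in% conserved_genes) expect_identical(cat_got, "conserved_mirna")
    else if (src %in% novel_genes) expect_identical(cat_got, "novel_input")
    else if (src %in% c("rrna", "trna", "snorna"))
      expect_identical(cat_got, src)
  }
  bg <- vapply(pre$tags$sequence, function(s)
    identical(truth_src[[s]], "background"), logical(1))
  expect_gte(mean(ann$records$category[bg] == "unannotated"), 0.99)
  # categories partition the tag set
  expect_identical(sum(ann$counts$unique_tags), nrow(pre$tags))
  expect_identical(sum(ann$counts$total_reads), sum(pre$tags$count))
})

test_that("annotation is invariant to tag input order", {
  sim <- tiny_sim(seed = 62, n_reads = 400)
  pre <- preprocess_fastq(sim$fastq, sim$config$adapter3)
  refs <- c(list(mature = sim$mature_refs), sim$ncrna_refs)
  a1 <- classify_tags(pre$tags, sim$genome, refs)
  perm <- pre$tags[rev(seq_len(nrow(pre$tags))), ]
  a2 <- classify_tags(perm, sim$genome, refs)
  m <- match(a1$records$tag_id, a2$records$tag_id)
  expect_identical(a1$records$category, a2$records$category[m])
  expect_identical(a1$counts, a2$counts)
})
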