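#!/usr/bin/env Rscript
# Step 7 — assemble the run summary.
#
# Collects the stage statistics, category percentages, length mode, novel
# candidate count, isomiR fractions and the qPCR 2^-ddCt table for the
# bundled synthetic plate into one JSON summary.

library(srnakit)

out <- "results"
stats <- read.delim("results/preprocess/stats.tsv")
s <- setNames(stats$count, stats$stage)
cat_tab <- read.delim("results/annotate/category_table.tsv")
ld <- read.delim("results/preprocess/length_distribution.tsv")
nov <- read.delim("results/novel/candidates.tsv")
frac <- read.delim("results/isomir/class_fractions.tsv")

qpcr <- read.delim(system.file("extdata", "qpcr_synthetic.tsv",
                               package = "srnakit"))
fc <- qpcr_fold_changes(qpcr, calibrator = "brain")
write.table(fc, file.path(out, "qpcr_fold_changes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

summary <- list(
  reads = as.list(s),
  high_quality_pct = percentage(s[["post_length"]], s[["raw_reads"]]),
  modal_length_nt = ld$length[which.max(ld$reads)],
  category_read_pct = setNames(as.list(cat_tab$pct_of_hq),
                               cat_tab$category),
  n_novel_candidates = nrow(nov),
  isomir_read_fractions = setNames(as.list(round(frac$read_fraction, 4)),
                                   frac$class)
)
jsonlite::write_json(summary, file.path(out, "run_summary.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/run_summary.json and results/qpcr_fold_changes.tsv\n")
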