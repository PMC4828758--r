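#!/usr/bin/env Rscript
# Step 6 — target-site prediction for the top novel candidates.
#
# Scans synthetic 3'UTRs (each carrying one planted site for a candidate:
# a perfect complement, an 8mer seed match with partial 3' support, and a
# seed-only site expected to be filtered) for seed matches, aligns each
# site as a miRNA:mRNA duplex, and keeps sites passing the score and
# duplex-energy thresholds.

library(srnakit)

out <- "results/targets"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
set.seed(20260926)

top <- read.delim("results/novel/top_candidates.tsv")
mirnas <- setNames(top$most_expressed_sequence, top$name)[
  seq_len(min(3L, nrow(top)))]

rand_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                              collapse = "")
utrs <- character(0); sites <- list()
for (nm in names(mirnas)) {
  m <- mirnas[[nm]]
  # planted site classes of decreasing strength
  utrs[paste0(nm, "_utr_perfect")] <-
    paste0(rand_rna(60), revcomp_rna(m), rand_rna(60))
  utrs[paste0(nm, "_utr_8mer")] <-
    paste0(rand_rna(60), revcomp_rna(substr(m, 10, nchar(m))), "UU",
           revcomp_rna(substr(m, 2, 8)), "A", rand_rna(60))
  utrs[paste0(nm, "_utr_seed_only")] <-
    paste0(rand_rna(60), revcomp_rna(substr(m, 2, 7)), rand_rna(60))
  for (u in grep(nm, names(utrs), value = TRUE))
    sites[[u]] <- scan_targets(m, utrs[[u]], mirna_id = nm, utr_id = u)
}
write_fasta(utrs, file.path(out, "utrs.fa"), space = "rna")

all_sites <- do.call(rbind, sites)
rownames(all_sites) <- NULL
write.table(all_sites[, setdiff(names(all_sites), "rendering")],
            file.path(out, "target_sites.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(unlist(lapply(seq_len(nrow(all_sites)), function(i) c(
  sprintf("> %s @ %s [%d-%d] %s  score %.1f  dG %.2f kcal/mol",
          all_sites$mirna_id[i], all_sites$utr_id[i], all_sites$start[i],
          all_sites$end[i], all_sites$site_type[i], all_sites$score[i],
          all_sites$energy[i]),
  all_sites$rendering[i], ""))), file.path(out, "alignments.txt"))

cat(sprintf("%d retained sites across %d synthetic UTRs for %d candidate miRNAs\n",
            nrow(all_sites), length(utrs), length(mirnas)))
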