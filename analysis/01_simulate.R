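#!/usr/bin/env Rscript
# Step 1 — simulate the small-RNA study library.
#
# Builds the toy genome with 20 planted miRNA hairpins (10 treated as known
# matures, 10 novel), the rRNA/tRNA/snoRNA reference sets, and a 50,000-read
# 3'-adapter-ligated FASTQ with known isomiR structure. All downstream steps
# read the files written here.

library(srnakit)

seed <- 1L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(rng_seed = seed)
sim <- simulate_library(cfg, fastq_path = file.path(out, "library.fastq"))

write_fasta(c(chr1 = sim$genome), file.path(out, "genome.fa"))
write_manifest_gff3(sim$manifest, file.path(out, "manifest.gff3"))
write.table(sim$manifest, file.path(out, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_fasta(sim$mature_refs, file.path(out, "mature_refs.fa"),
            space = "rna")
for (cl in names(sim$ncrna_refs))
  write_fasta(sim$ncrna_refs[[cl]], file.path(out, paste0(cl, "_refs.fa")),
              space = "rna")

cat(sprintf("library: %d reads, %d planted miRNA genes (%d known), mode insert length %d nt\n",
            cfg$n_reads, cfg$n_mirna_genes, cfg$n_conserved_mirnas,
            as.integer(names(which.max(table(sim$truth$insert_len[
              sim$truth$source != "background"]))))))
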