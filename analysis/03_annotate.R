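#!/usr/bin/env Rscript
# Step 3 — hierarchical annotation of unique tags.
#
# Each tag gets exactly one category with precedence conserved miRNA >
# rRNA > tRNA > snoRNA; reference-free tags that map to the genome
# (<= 1 mismatch, both strands) become novel-discovery input, the rest are
# unannotated. Writes per-tag records, the category table with percentages
# of the high-quality total, and the genome alignments of novel-input tags.

library(srnakit)

out <- "results/annotate"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tags <- read.delim("results/preprocess/tags.tsv")
genome <- read_fasta("results/sim/genome.fa", space = "dna")[[1]]
ref_sets <- list(mature = read_fasta("results/sim/mature_refs.fa"),
                 rrna = read_fasta("results/sim/rrna_refs.fa"),
                 trna = read_fasta("results/sim/trna_refs.fa"),
                 snorna = read_fasta("results/sim/snorna_refs.fa"))

ann <- classify_tags(tags, genome, ref_sets)

stats <- read.delim("results/preprocess/stats.tsv")
hq <- stats$count[stats$stage == "post_length"]
cat_tab <- category_stats(ann$counts, hq)

write.table(ann$records, file.path(out, "records.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cat_tab, file.path(out, "category_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ann$alignments, file.path(out, "novel_input_alignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

print(cat_tab, row.names = FALSE)
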