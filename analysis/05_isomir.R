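#!/usr/bin/env Rscript
# Step 5 — isomiR classification and summary statistics.
#
# Tags annotated as conserved miRNAs are aligned end-anchored to their
# assigned mature sequence and classified into the 5'/internal/3' isomiR
# taxonomy (trimming, templated extension, non-templated A/U addition,
# substitutions in or out of the seed). Fractions are read-weighted.

library(srnakit)

out <- "results/isomir"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tags <- read.delim("results/preprocess/tags.tsv")
records <- read.delim("results/annotate/records.tsv")
manifest <- read.delim("results/sim/manifest.tsv")
genome <- read_fasta("results/sim/genome.fa", space = "dna")[[1]]

con <- records[records$category == "conserved_mirna", ]
idx <- match(con$tag_id, tags$tag_id)
assignments <- data.frame(tag_id = con$tag_id,
                          sequence = tags$sequence[idx],
                          count = tags$count[idx],
                          mirna_id = con$reference_id,
                          stringsAsFactors = FALSE)
canon <- setNames(manifest$mature_seq, manifest$gene_id)
contexts <- mirna_contexts(list(genome = genome, manifest = manifest))

recs <- isomir_records(assignments, canon, contexts)
write.table(recs, file.path(out, "isomir_records.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

s <- summarize_isomirs(recs)
frac <- data.frame(class = names(s$class_fractions),
                   read_fraction = as.numeric(s$class_fractions),
                   tag_fraction = as.numeric(s$class_fractions_tag))
write.table(frac, file.path(out, "class_fractions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(s$per_mirna, file.path(out, "per_mirna.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

nc <- s$noncanonical_fractions
cat(sprintf("among isomiR reads: 3' %.2f%%, 5' %.2f%%, internal %.2f%%; trimming is %.2f%% of 3' isomiRs\n",
            100 * nc[["iso3"]], 100 * nc[["iso5"]], 100 * nc[["internal"]],
            100 * s$iso3_trim_share))
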