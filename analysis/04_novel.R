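#!/usr/bin/env Rscript
# Step 4 — hairpin-based novel miRNA discovery.
#
# Clusters the genome alignments of novel-input tags, excises candidate
# windows under both arm hypotheses, folds progressively extended precursor
# subsequences, applies the stem-loop and read-support criteria, and names
# the accepted candidates Novel-1, Novel-2, ... (letter suffixes for shared
# mature sequences). Also reports how many planted novel loci were
# recovered.

library(srnakit)

out <- "results/novel"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tags <- read.delim("results/preprocess/tags.tsv")
genome <- read_fasta("results/sim/genome.fa", space = "dna")[[1]]
aln <- read.delim("results/annotate/novel_input_alignments.tsv")

nov <- find_novel_mirnas(tags, aln, genome)

flat <- nov[, setdiff(names(nov), "supporting")]
write.table(flat, file.path(out, "candidates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_candidates_gff3(nov, file.path(out, "candidates.gff3"))

tab <- top_novel_table(nov, tags, n = 10L)
write.table(tab, file.path(out, "top_candidates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

man <- read.delim("results/sim/manifest.tsv")
man <- man[!man$conserved, ]
recovered <- vapply(seq_len(nrow(man)), function(i) {
  m <- man[i, ]
  any(nov$strand == m$strand & nov$start < m$pre_end & nov$end > m$pre_start)
}, logical(1))

cat(sprintf("%d candidates accepted; %d/%d planted novel loci recovered\n",
            nrow(nov), sum(recovered), nrow(man)))
print(tab[, c("name", "total_count", "n_isomirs",
              "most_expressed_sequence", "length",
              "most_expressed_count", "seed")], row.names = FALSE)
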