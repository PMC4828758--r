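Package: srnakit
Title: Small RNA-Seq Annotation, Novel miRNA Discovery and isomiR Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained small RNA sequencing analysis toolkit: synthetic
    small-RNA library simulation with ground-truth isomiR structure, FASTQ
    preprocessing (quality, adapter and length filtering, read collapsing),
    hierarchical annotation of unique tags against genome and ncRNA reference
    sets, hairpin-based novel miRNA discovery with a weighted Nussinov folding
    engine, isomiR classification into 5', internal and 3' variant classes,
    seed-match target-site prediction with duplex alignment and nearest-neighbor
    duplex energies, and summary reporting including 2^-ddCt qPCR arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
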