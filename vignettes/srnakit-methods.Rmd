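---
title: "Methods: small RNA-seq annotation, novel miRNA discovery and isomiR analysis with srnakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA-seq annotation, novel miRNA discovery and isomiR analysis with srnakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

srnakit is a self-contained reimplementation of a deep-sequencing small-RNA
analysis: from raw adapter-ligated reads to annotated unique tags, novel
miRNA candidates supported by hairpin structure and read evidence, an
isomiR census, and miRNA target-site predictions. Because the original
sequencing library and the reference genome of the study organism are far
beyond desk scale, the package ships a first-class synthetic-data module
that emulates the essential features of such a library with known ground
truth, and every stage is validated against independent oracles and
parameter-recovery experiments on that synthetic data. This vignette
documents the models, the tunable parameters, the numerical choices, and
what the tests do and do not establish about behavior on real data.

## The synthetic library

`sim_config()` fixes the study conditions. A 50 kb single-chromosome toy
genome receives 20 planted miRNA hairpin precursors: a mature arm of
20-24 nt (drawn with mode 22 nt, matching the dominant size class of real
vertebrate small-RNA libraries), a terminal loop of 8-15 nt, and a star arm
that is the reverse complement of the mature arm with per-position
deviations at `stem_mismatch_rate` (default 0.08, a typical imperfection
level for animal pre-miRNA stems). Arm (5p/3p) and strand are random; loci
are spaced at least 400 nt apart so that discovery windows never mix loci.
Half of the genes (10) are declared "known": their matures form the
reference set the annotator treats as conserved miRNAs, while the other
half exercise novel discovery.

Reads are a mixture: 10% random background of 15-35 nt (exercising both
sides of the length filter), 25% fragments of synthetic rRNA/tRNA/snoRNA
references (rRNA-dominated, as in real total-RNA libraries), and the rest
miRNA reads drawn from a per-gene log-normal expression profile
(mu = 2, sigma = 1), which reproduces the heavy-tailed counts seen in
deep-sequencing candidate tables (hundreds to tens of thousands of reads
per gene). Each miRNA read passes through the isomiR generator
(`apply_isomir()`): canonical sequence, 3'/5' trimming with geometric
lengths, templated 3' extension copied from the genomic flank,
non-templated 3' A/U addition chosen not to match the flank (so the edit is
identifiable from sequence alone), a 1-nt 5' shift, or a single internal
substitution. The published study reports no generative rates — isomiR
frequencies are an output, not an input, of such experiments — so the
default mixture (55% canonical, 3'-dominated variation) was chosen once for
testability: every class occurs often enough to be exercised, and 3'
variants dominate as they do in real animal libraries. Inserts get the
TruSeq small-RNA 3' adapter, random padding to a 50 nt read, per-base
substitution errors at 0.5% (low-quality scores at error positions,
Q30-40 elsewhere), and Phred+33 qualities. The 5' adapter is modeled as
already removed, since the analysis operates on insert sequences.

The generator does not model quality decay by cycle, PCR duplicates, or
multi-tissue expression structure (the emulated study pooled tissues into
one library). Passing tests therefore demonstrate correctness of the
algorithms under a realistic but idealized error model, not robustness to
instrument-specific artifacts.

## Preprocessing

`preprocess_fastq()` applies, in order: a quality filter (mean Phred >= 20
and no N bases — the concrete reading of "low-quality tag" filtering, which
the original pipeline left unspecified), exact leftmost 3'-adapter-prefix
trimming with a minimum overlap of 6 nt, an inclusive 18-30 nt length
filter (boundary semantics follow the strict inequalities of the rule
"remove < 18 nt or > 30 nt"), and collapsing to U-normalized unique tags
ordered by descending count then sequence — so tag identifiers are
deterministic and order-independent. Adapter matching is exact by design:
it keeps the stage an oracle-checkable string operation; mismatch-tolerant
trimming would change counts by well under the error rate at these read
lengths.

## Hierarchical annotation

Each tag receives exactly one category with precedence
conserved miRNA > rRNA > tRNA > snoRNA > other ncRNA > novel input >
unannotated. Conserved assignment aligns the tag to each known mature
allowing up to 2 substitutions and end offsets up to ±3 nt per end — the
offset allowance admits terminal isomiRs, which real accounting assigns to
their parent miRNA — with the overlap required to cover the reference seed
(positions 2-8). ncRNA assignment is mismatch-tolerant containment
(<= 1 substitution) in the reference sets; genome mapping is ungapped with
<= 1 substitution on both strands, all hits retained. The mismatch scan is
compiled (exhaustive over every offset), and the test suite checks it
against an independent R scan over 1,000 random cases; at toy scale
exhaustive containment is exact and deterministic, which is why no
heuristic aligner is used. The miRNA-first precedence is a design choice:
category tables in this field list conserved miRNAs separately from
structural-RNA classes, implying miRNA assignment is not preempted.
"One mismatch" genome mapping is interpreted as one substitution anywhere
in the tag; a seed-restricted reading is available via the matcher
parameters.

## Novel miRNA discovery

Novel-input tag alignments are clustered per strand (gap <= 10 nt merged),
anchored at the highest-count tag, and two windows are excised per cluster
covering the two arm hypotheses (20 nt proximal / 150 nt distal flank —
standard excision geometry; the emulated study states none). Windows from
minus-strand clusters are reverse-complemented so the mature is always
5'->3'.

Folding is a weighted Nussinov dynamic program (G-C 3, A-U 2, G-U 1,
minimum loop 3, deterministic traceback), implemented in C++ and verified
against brute-force enumeration of all nested structures for short
sequences. It replaces a thermodynamic folder deliberately: it is
self-contained, exactly testable, and adequate for hairpin-shape decisions
at these scales. The evaluation interface accepts any folder returning the
same structure, so a thermodynamic backend can be substituted.

A maximum-pairing objective has a known pathology: it decorates random
sequence with isolated 1-3 bp helices and, on a 190 nt window, essentially
always produces multibranched structures, so naive "is the window fold an
unbranched stem-loop" testing rejects every real locus. The evaluator
therefore works the way excision-based discovery tools do:

1. candidate precursor subsequences anchored at the mature read and
   extending progressively toward the distal flank (extensions of
   mature length + 12 to + 52 nt in 5 nt steps) are folded one at a time;
2. helices shorter than 4 stacked pairs are disregarded — with an 8% stem
   mismatch rate real stems yield helix runs of ~12 bp, while random
   sequence rarely sustains 4 consecutive pairs in these window sizes;
3. the remaining pairs must show a coherent mature:star duplex — the
   mature's pairs form one nested chain whose partners fall in a compact
   star region no wider than the mature length + 8 nt (bulge allowance);
4. the mature must lie on one arm (no self-pairing, no partners on both
   sides, a terminal loop of >= 3 nt);
5. at least 60% of mature bases must be paired; and
6. at least 2 distinct tags must start within ±3 nt of the mature or star
   5' end — the read-support rule that defines a high-probability
   candidate, with the star position computed from the pair list with the
   canonical 2 nt 3' overhang.

Only the >= 2-distinct-reads rule comes from the emulated study; the 60%
pairing fraction, ±3 nt position tolerance, helix and compactness
parameters are this package's own operating points, selected during method
development by maximizing separation between planted loci and
dinucleotide-shuffled windows (Altschul-Erickson shuffling, preserving
dinucleotide composition so folding propensity is not trivially destroyed).
At the defaults the package recovers >= 90% of planted novel loci with two
or more distinct supporting tags at the default library size while
accepting < 5% of shuffled windows; both numbers are recomputed by the test
suite and the acceptance script, not quoted. Accepted candidates are named
Novel-1, Novel-2, ... by descending support, with letter suffixes for
distinct loci sharing an identical mature sequence (as real candidate
tables do for paralogous loci). A candidate's mature sequence is taken from
the genome under the anchor alignment, so the reported mature is always a
substring of its precursor even when the anchor tag carries a mapping
mismatch.

## isomiR classification

A tag assigned to a miRNA is aligned to the canonical mature end-anchored
and ungapped: over all 5'/3' end-offset pairs within ±5 nt consistent with
the tag length, the pair minimizing substitutions in the overlap wins (ties
to the smallest |5'| then |3'| offset); more than 2 substitutions is an
assignment error. The ±5 cap is a judgment call: beyond it, calling the tag
a variant of that miRNA is dubious. Classes follow the standard taxonomy —
iso5 (5' offset), iso3 (3' offset), internal (substitutions only), mixed
(edits at both ends; unnamed in the usual three-way diagrams but required
for the classification to be total). Extensions are templated iff every
added base matches the precursor/genomic flank; non-templated 3' additions
record the added nucleotide (A/U/other), since adenylation and uridylation
are the biologically meaningful cases. Substitutions carry an in-seed flag
(canonical positions 2-8). Summary fractions are read-weighted to match the
percentage style of published isomiR tables, with tag-weighted fractions
alongside; fractions are invariant to record order and to splitting a tag's
count across duplicate records.

The parameter-recovery experiment regenerates a 50,000-read library with
known rates (60% canonical, 30% 3' trimming, 5% 5' shift,
5% substitution), with sequencing error off and tags assigned by ground
truth, and requires each recovered fraction to land within 3 binomial
standard errors of its generative rate and every per-read class label to
match the truth table exactly. Sequencing error is disabled there because a
0.5% per-base error converts ~10% of reads into spurious
substitution-carriers — the experiment isolates the classifier, not the
error model; with errors on, the internal fraction rises accordingly, as
the acceptance script's default-condition numbers show.

## Target scanning

`find_seed_sites()` scans a 3'UTR for Watson-Crick reverse-complement
matches to miRNA positions 2-7 and types each occurrence (6mer, 7mer-m8,
7mer-A1, 8mer) using the canonical definitions: position 8 pairs the base
5' of the core match on the UTR, and the A of 7mer-A1/8mer sits opposite
position 1 regardless of complementarity. `align_duplex()` then aligns the
full miRNA against the site-containing window, antiparallel, with
complementarity scoring (+5 Watson-Crick, +2 G:U, −3 mismatch, −8/−2
affine gaps) and the match/mismatch scores at seed positions 2-8 scaled
×4 — the convention of alignment-based target predictors, under which a
perfect 22 nt duplex scores 215 and a bare 6mer cannot reach the default
140 score threshold. The miRNA is aligned end to end; UTR overhangs of the
window are free. The rendering uses `|` for Watson-Crick pairs, `:` for
G:U wobbles and `-` for gaps, and re-parses to the identical pair
classification (a tested round trip).

Duplex free energy is a nearest-neighbor sum over consecutively stacked
pairs using an embedded Turner-style stacking table (Watson-Crick and G:U
wobble entries, kcal/mol at 37°C), +4 kcal/mol per interior loop or bulge
and +4.1 kcal/mol duplex initiation; no pairs means 0. This is a ranking
energy for toy duplexes, not a partition-function model: it ignores
dangling ends, terminal-AU penalties and loop-size dependence. Sites are
retained at score >= 140 and energy <= −14 kcal/mol, both exposed as
parameters. The four external predictors the emulated study combined are
neither wrapped nor reimplemented; this one in-repo scorer replaces them,
and the study's specific gene predictions are out of scope because those
UTR sequences are not available in print.

## Reporting

`percentage()` rounds half-up to two decimals, the convention that
reproduces the published read-statistics percentages exactly from their
printed counts; the denominator for category percentages is the
high-quality (18-30 nt) read total, which is the only reading that makes
the published rRNA/tRNA/snoRNA percentages internally consistent.
`length_distribution()` is read-weighted with ties broken toward the
shorter length (documented, arbitrary). `top_novel_table()` reports
candidates by their most-expressed sequence with computed length and seed;
the published table it mirrors sorts ascending by that count and titles
itself "10 most frequent" while listing 16 rows — output here defaults to
descending with a flag, and one published row prints a length inconsistent
with its own printed sequence, which the package resolves in favor of the
sequence. `ddct()` implements 2^−ΔΔCt relative quantification;
`qpcr_fold_changes()` summarizes replicates as mean ± standard error by
default (the study's methods text specifies SE while a figure caption says
SD; SE was chosen, switchable via `spread = "sd"`).

## Numerical and testing choices

Problem sizes were chosen so the whole suite runs in minutes: folding
oracles enumerate structures up to 14 nt (200 cases), matching oracles
cover 1,000 random cases against a 3 kb genome, duplex-DP cross-checks run
500 random miRNA-UTR pairs, and the two simulation experiments use the
default 50,000-read library. Every stochastic test fixes its seed; the
acceptance script takes `--seed` and derives all internal seeds from it.
All coordinates are 0-based half-open internally with 1-based inclusive
GFF3 on output; all sequences are RNA-space (U) internally with DNA
accepted on input.

Known limitations: the Nussinov objective can fold a heavily mismatched
planted stem into an alternative structure (at the default 8% stem
mismatch rate this costs an occasional locus, which is why the
clean-construction test plants mismatch-free stems and the recovery
criterion is >= 90%, not 100%); multi-locus tags are retained at all loci,
which can report a star-arm twin of a true locus as a separate candidate
(as paralog-suffixed names in real tables do); and the energy model ranks
rather than predicts absolute stabilities.
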