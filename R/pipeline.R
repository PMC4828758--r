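#' Run the full small-RNA analysis pipeline on a simulated library
#'
#' Convenience orchestration used by the analysis scripts: simulate (or
#' accept) a library, preprocess, classify, discover novel miRNAs, classify
#' isomiRs of conserved-assigned tags, and assemble summary tables.
#'
#' @param config a [sim_config()]; ignored when `sim` is supplied.
#' @param sim an existing [simulate_library()] result.
#' @return list: `sim`, `pre` (preprocess result), `annotation`
#'   (classification result), `novel` (named candidates), `isomirs`
#'   (records for conserved-assigned tags), `isomir_summary` (or NULL),
#'   `length_dist`, `category_table`.
#' @export
run_pipeline <- function(config = sim_config(), sim = NULL) {
  if (is.null(sim)) sim <- simulate_library(config)
  cfg <- sim$config
  pre <- preprocess_fastq(sim$fastq, cfg$adapter3)
  ref_sets <- c(list(mature = sim$mature_refs), sim$ncrna_refs)
  ann <- classify_tags(pre$tags, sim$genome, ref_sets)
  novel <- find_novel_mirnas(pre$tags, ann$alignments, sim$genome)

  # isomiR records of tags assigned to the known matures
  con <- ann$records$category == "conserved_mirna"
  isom <- NULL; isum <- NULL
  if (any(con)) {
    idx <- match(ann$records$tag_id[con], pre$tags$tag_id)
    assignments <- data.frame(
      tag_id = pre$tags$tag_id[idx],
      sequence = pre$tags$sequence[idx],
      count = pre$tags$count[idx],
      mirna_id = ann$records$reference_id[con],
      stringsAsFactors = FALSE)
    contexts <- mirna_contexts(sim)
    isom <- isomir_records(assignments, sim$mature_refs, contexts)
    isum <- summarize_isomirs(isom)
  }

  hq_total <- pre$stats$count[pre$stats$stage == "post_length"]
  cat_table <- category_stats(ann$counts, max(hq_total, 1))
  ld <- length_distribution(pre$tags)

  list(sim = sim, pre = pre, annotation = ann, novel = novel,
       isomirs = isom, isomir_summary = isum, length_dist = ld,
       category_table = cat_table)
}

#' Precursor-with-flank contexts for the planted miRNA genes
#'
#' @param sim a [simulate_library()] result.
#' @return named RNA vector (gene_id -> precursor with 10-nt genomic
#'   flanks, gene orientation).
#' @export
mirna_contexts <- function(sim) {
  man <- sim$manifest
  ctx <- character(nrow(man))
  for (i in seq_len(nrow(man))) {
    s <- man$pre_start[i] - 10L
    e <- man$pre_end[i] + 10L
    sub <- substr(sim$genome, s + 1L, e)
    ctx[i] <- if (man$strand[i] == "+") as_rna(sub)
              else revcomp_rna(as_rna(sub))
  }
  stats::setNames(ctx, man$gene_id)
}
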