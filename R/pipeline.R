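# End-to-end genome-pair orchestration: protein scoring -> isoform-pair
# selection -> candidate filter -> nucleotide conservation -> microsynteny
# -> ortholog decision, with per-stage logging and TSV reporting.

.log_stage <- function(verbose, ...) if (verbose) message(sprintf(...))

#' Run the full ortholog pipeline on a genome pair
#'
#' Executes every stage of the method on two annotated genomes and returns
#' the full results table: one row per candidate homolog pair with all
#' computed metrics and the ortholog decision. Deterministic: identical
#' inputs yield identical output.
#'
#' @param query_genome,subject_genome [annotated_genome()] objects.
#' @param config an [ortholog_config()].
#' @param alignments optional precomputed isoform-level alignment table in
#'   the format of [all_vs_all_protein_scores()] (e.g. parsed from an
#'   external search tool with [read_alignment_table()]); computed with the
#'   bundled aligner when `NULL`.
#' @param verbose log per-stage counts with [message()].
#' @return List with `report` (data.frame, one row per candidate pair:
#'   gene/isoform ids, `raw_protein_score`, `jaccard_protein`,
#'   `coverage_longer`, `coverage_shorter`, `jaccard_nt`, `n_syntenic`,
#'   `is_ortholog`, `rule_fired`) and `ortholog_pairs` (data.frame
#'   `query_gene_id`/`subject_gene_id` of accepted one-to-one calls).
#' @export
run_pair_pipeline <- function(query_genome, subject_genome,
                              config = ortholog_config(),
                              alignments = NULL, verbose = FALSE) {
  stopifnot(inherits(query_genome, "annotated_genome"),
            inherits(subject_genome, "annotated_genome"))
  qprot <- setNames(query_genome$isoforms$protein_seq,
                    query_genome$isoforms$isoform_id)
  sprot <- setNames(subject_genome$isoforms$protein_seq,
                    subject_genome$isoforms$isoform_id)
  .log_stage(verbose, "proteins: %d query, %d subject", length(qprot),
             length(sprot))

  q_self <- self_alignment_scores(qprot, config)
  s_self <- self_alignment_scores(sprot, config)
  if (is.null(alignments))
    alignments <- all_vs_all_protein_scores(qprot, sprot, config)
  .log_stage(verbose, "isoform alignments above floor: %d", nrow(alignments))

  pairs <- gene_pair_scores(alignments, query_genome, subject_genome,
                            q_self, s_self)
  cand <- candidate_homolog_pairs(pairs, config$candidate_ratio)
  .log_stage(verbose, "gene pairs: %d scored, %d candidates", nrow(pairs),
             nrow(cand))

  cand <- add_nucleotide_scores(cand, query_genome, subject_genome, config)
  cand <- add_synteny_scores(cand, query_genome, subject_genome, config)
  calls <- call_orthologs(cand, query_genome, subject_genome, config)
  if (verbose) {
    tab <- table(calls$rule_fired[calls$accepted])
    .log_stage(verbose, "accepted calls: %d (%s)", sum(calls$accepted),
               paste(names(tab), tab, sep = "=", collapse = ", "))
  }

  report <- data.frame(
    query_gene_id = calls$query_gene_id,
    subject_gene_id = calls$subject_gene_id,
    query_isoform_id = calls$query_isoform_id,
    subject_isoform_id = calls$subject_isoform_id,
    raw_protein_score = calls$raw_score,
    jaccard_protein = calls$jaccard_protein,
    coverage_longer = calls$coverage_longer,
    coverage_shorter = calls$coverage_shorter,
    jaccard_nt = calls$jaccard_nt,
    n_syntenic = calls$n_syntenic,
    is_ortholog = calls$accepted,
    rule_fired = calls$rule_fired,
    stringsAsFactors = FALSE)
  acc <- report[report$is_ortholog, c("query_gene_id", "subject_gene_id")]
  rownames(acc) <- NULL
  list(report = report, ortholog_pairs = acc)
}

#' Write the full results table
#'
#' Tab-separated, fixed 12-column header matching the report of
#' [run_pair_pipeline()]; floating-point metrics at 4 decimals; rows in the
#' deterministic report order (query gene rank, then subject).
#'
#' @param report report data.frame from [run_pair_pipeline()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pair_report <- function(report, path) {
  d <- report
  for (col in c("jaccard_protein", "coverage_longer", "coverage_shorter",
                "jaccard_nt"))
    d[[col]] <- sprintf("%.4f", d[[col]])
  d$is_ortholog <- ifelse(d$is_ortholog, "true", "false")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write accepted ortholog pairs as an exchange TSV
#'
#' Five-column layout modeled on the public gene_orthologs exchange file:
#' `tax_id`, `GeneID`, `relationship`, `Other_tax_id`, `Other_GeneID`, with
#' relationship fixed to `"Ortholog"`.
#'
#' @param pairs data.frame (`query_gene_id`, `subject_gene_id`).
#' @param path output file.
#' @param query_tax_id,subject_tax_id numeric or string taxon labels for the
#'   two genomes.
#' @return `path`, invisibly.
#' @export
write_ortholog_pairs <- function(pairs, path, query_tax_id = "query",
                                 subject_tax_id = "subject") {
  d <- data.frame(tax_id = query_tax_id,
                  GeneID = pairs$query_gene_id,
                  relationship = "Ortholog",
                  Other_tax_id = subject_tax_id,
                  Other_GeneID = pairs$subject_gene_id,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ortholog-pair exchange TSV
#'
#' Inverse of [write_ortholog_pairs()].
#'
#' @param path TSV written by [write_ortholog_pairs()].
#' @return data.frame (`query_gene_id`, `subject_gene_id`).
#' @export
read_ortholog_pairs <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(query_gene_id = as.character(d$GeneID),
             subject_gene_id = as.character(d$Other_GeneID),
             stringsAsFactors = FALSE)
}
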