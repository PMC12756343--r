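#' Modified Jaccard index on alignment scores
#'
#' Normalizes a raw alignment score against the potential maximum similarity
#' of the pair: `s_xy / (s_xx + s_yy - s_xy)`, where `s_xx` and `s_yy` are
#' the self-alignment scores. Equals 1 exactly when the pair aligns as well
#' as each sequence aligns to itself, and 0 when there is no similarity.
#' Vectorized over its arguments.
#'
#' @param s_xy raw alignment score(s), `0 <= s_xy <= min(s_xx, s_yy)`.
#' @param s_xx,s_yy positive self-alignment scores.
#' @return Numeric ratio(s) in `[0, 1]`.
#' @export
modified_jaccard_protein <- function(s_xy, s_xx, s_yy) {
  if (any(s_xx <= 0) || any(s_yy <= 0))
    stop("self scores must be positive", call. = FALSE)
  if (any(s_xy < 0) || any(s_xy > pmin(s_xx, s_yy)))
    stop("alignment score outside [0, min(self scores)]: scores inconsistent",
         call. = FALSE)
  s_xy / (s_xx + s_yy - s_xy)
}

# Annotate isoform-level alignments with gene ids and protein Jaccard.
.alignments_with_genes <- function(alignments, query_genome, subject_genome,
                                   query_self, subject_self) {
  qiso <- query_genome$isoforms
  siso <- subject_genome$isoforms
  mq <- match(alignments$query_protein_id, qiso$isoform_id)
  ms <- match(alignments$subject_protein_id, siso$isoform_id)
  if (anyNA(mq) || anyNA(ms))
    stop("alignment references unknown isoform(s)", call. = FALSE)
  a <- alignments
  a$query_gene_id <- qiso$gene_id[mq]
  a$subject_gene_id <- siso$gene_id[ms]
  a$self_score_query <- unname(query_self[a$query_protein_id])
  a$self_score_subject <- unname(subject_self[a$subject_protein_id])
  a$jaccard_protein <- modified_jaccard_protein(
    pmin(a$raw_score, pmin(a$self_score_query, a$self_score_subject)),
    a$self_score_query, a$self_score_subject)
  qlen <- nchar(qiso$protein_seq)[mq]
  slen <- nchar(siso$protein_seq)[ms]
  q_longer <- qlen >= slen
  a$coverage_longer <- ifelse(q_longer, a$aligned_query_fraction,
                              a$aligned_subject_fraction)
  a$coverage_shorter <- ifelse(q_longer, a$aligned_subject_fraction,
                               a$aligned_query_fraction)
  a
}

#' Best isoform pair per gene pair
#'
#' Reduces isoform-level alignments to one record per (query gene, subject
#' gene): the isoform pair with the highest protein modified Jaccard
#' represents the gene pair. Exact ties are broken by the lexicographically
#' smallest (query isoform id, subject isoform id) for determinism.
#'
#' @param alignments data.frame from [all_vs_all_protein_scores()] (isoform
#'   identifiers in the protein id columns).
#' @param query_genome,subject_genome the two [annotated_genome()] objects.
#' @param query_self,subject_self named self-score vectors from
#'   [self_alignment_scores()].
#' @return data.frame with one row per gene pair: gene and isoform ids, raw
#'   score, self scores, `jaccard_protein`, and the coverage of the longer
#'   and shorter protein of the chosen pair.
#' @export
gene_pair_scores <- function(alignments, query_genome, subject_genome,
                             query_self, subject_self) {
  cols <- c("query_gene_id", "subject_gene_id", "query_isoform_id",
            "subject_isoform_id", "raw_score", "self_score_query",
            "self_score_subject", "jaccard_protein", "coverage_longer",
            "coverage_shorter")
  if (nrow(alignments) == 0L) {
    out <- data.frame(query_gene_id = character(), subject_gene_id = character(),
                      query_isoform_id = character(), subject_isoform_id = character(),
                      raw_score = numeric(), self_score_query = numeric(),
                      self_score_subject = numeric(), jaccard_protein = numeric(),
                      coverage_longer = numeric(), coverage_shorter = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  a <- .alignments_with_genes(alignments, query_genome, subject_genome,
                              query_self, subject_self)
  a$query_isoform_id <- a$query_protein_id
  a$subject_isoform_id <- a$subject_protein_id
  a <- a[order(a$query_gene_id, a$subject_gene_id, -a$jaccard_protein,
               a$query_isoform_id, a$subject_isoform_id), , drop = FALSE]
  key <- paste(a$query_gene_id, a$subject_gene_id, sep = "\r")
  out <- a[!duplicated(key), cols, drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best isoform pair for one gene pair
#'
#' Convenience wrapper of [gene_pair_scores()] restricted to a single pair of
#' genes; returns `NULL` when no isoform alignment exists between them.
#'
#' @inheritParams gene_pair_scores
#' @param query_gene,subject_gene gene identifiers.
#' @return One-row data.frame as in [gene_pair_scores()], or `NULL`.
#' @export
best_isoform_pair <- function(query_gene, subject_gene, alignments,
                              query_genome, subject_genome,
                              query_self, subject_self) {
  qiso <- query_genome$isoforms$isoform_id[
    query_genome$isoforms$gene_id == query_gene]
  siso <- subject_genome$isoforms$isoform_id[
    subject_genome$isoforms$gene_id == subject_gene]
  a <- alignments[alignments$query_protein_id %in% qiso &
                    alignments$subject_protein_id %in% siso, , drop = FALSE]
  if (nrow(a) == 0L) return(NULL)
  gene_pair_scores(a, query_genome, subject_genome, query_self, subject_self)
}

#' Candidate homolog pairs within 20% of the best score
#'
#' Filters gene-level pair scores to the candidate set: a pair (X, Y) is
#' retained when its protein modified Jaccard is within the configured
#' fraction (default 80%) of the best score for X **or** of the best score
#' for Y. Every gene's best-scoring pair is therefore always retained.
#'
#' @param pair_scores data.frame from [gene_pair_scores()].
#' @param ratio retention threshold as a fraction of the best score
#'   (default `0.8`, i.e. within 20% of the best).
#' @return The filtered data.frame with class `candidate_table`, ordered by
#'   query then subject gene id.
#' @export
candidate_homolog_pairs <- function(pair_scores, ratio = 0.8) {
  d <- as.data.frame(pair_scores, stringsAsFactors = FALSE)
  if (nrow(d)) {
    best_q <- tapply(d$jaccard_protein, d$query_gene_id, max)
    best_s <- tapply(d$jaccard_protein, d$subject_gene_id, max)
    keep <- d$jaccard_protein >= ratio * best_q[d$query_gene_id] |
      d$jaccard_protein >= ratio * best_s[d$subject_gene_id]
    d <- d[keep, , drop = FALSE]
    d <- d[order(d$query_gene_id, d$subject_gene_id), , drop = FALSE]
    rownames(d) <- NULL
  }
  class(d) <- c("candidate_table", "data.frame")
  d
}

#' @export
print.candidate_table <- function(x, ...) {
  cat(sprintf("candidate_table: %d pair(s), %d query / %d subject gene(s)\n",
              nrow(x), length(unique(x$query_gene_id)),
              length(unique(x$subject_gene_id))))
  NextMethod()
}
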