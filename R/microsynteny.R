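# Microsynteny: conservation of local gene content around a candidate pair,
# counted as homologous neighbor pairs within a 20-locus neighborhood
# (at most `k = 10` adjacent loci per side of each focal gene).

#' Neighborhood of a gene locus
#'
#' Up to `k` loci with smaller rank and up to `k` with larger rank on the
#' same scaffold, in rank order, excluding the focal locus. Windows never
#' span scaffolds.
#'
#' @param genome an [annotated_genome()].
#' @param gene_id focal gene.
#' @param k maximum adjacent loci per side (default 10).
#' @return Character vector of neighbor gene ids in rank order.
#' @export
neighborhood <- function(genome, gene_id, k = 10L) {
  g <- genome$genes[genome$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1L) stop("unknown gene: ", gene_id, call. = FALSE)
  same <- genome$genes[genome$genes$scaffold_id == g$scaffold_id, , drop = FALSE]
  nb <- same[same$rank >= g$rank - k & same$rank <= g$rank + k &
               same$gene_id != gene_id, , drop = FALSE]
  nb$gene_id[order(nb$rank)]
}

#' Microsynteny score of a candidate pair
#'
#' Counts homologous gene pairs between the neighborhoods of the two focal
#' genes: pairs (q, s) with q in the query gene's window, s in the subject
#' gene's window, and (q, s) present in the candidate homolog table.
#' Neighbors are matched one-to-one, greedily in rank order (each query
#' neighbor takes its lowest-rank unmatched subject partner), so a single
#' duplicated neighbor cannot inflate the count. The score is bounded by
#' `2 * k` (20 by default) and by the smaller window.
#'
#' @param query_gene,subject_gene the focal candidate pair.
#' @param query_genome,subject_genome the two [annotated_genome()] objects.
#' @param candidates a `candidate_table` from [candidate_homolog_pairs()]
#'   (homology = membership in the candidate set, not final ortholog calls).
#' @param k window half-width in loci (default 10).
#' @return Integer microsynteny count `N`.
#' @export
microsynteny_score <- function(query_gene, subject_gene,
                               query_genome, subject_genome,
                               candidates, k = 10L) {
  qn <- neighborhood(query_genome, query_gene, k)
  sn <- neighborhood(subject_genome, subject_gene, k)
  if (!length(qn) || !length(sn)) return(0L)
  partners <- split(candidates$subject_gene_id, candidates$query_gene_id)
  s_rank <- setNames(subject_genome$genes$rank, subject_genome$genes$gene_id)
  used <- character()
  n <- 0L
  for (q in qn) {                       # qn already in rank order
    cand <- intersect(partners[[q]], setdiff(sn, used))
    if (length(cand)) {
      pick <- cand[order(s_rank[cand], cand)][1L]
      used <- c(used, pick)
      n <- n + 1L
    }
  }
  n
}

# Annotate a candidate table with n_syntenic for every pair.
add_synteny_scores <- function(candidates, query_genome, subject_genome,
                               config = ortholog_config()) {
  k <- config$synteny_window
  n <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates)))
    n[i] <- microsynteny_score(candidates$query_gene_id[i],
                               candidates$subject_gene_id[i],
                               query_genome, subject_genome, candidates, k)
  candidates$n_syntenic <- n
  candidates
}
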