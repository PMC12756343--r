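# The dual-strategy ortholog decision. Every candidate pair (X, Y) is judged
# against its competing pairs — all candidate pairs sharing X or Y. With
# microsynteny support (N >= 1) any one of rules S1-S4 accepts the pair; with
# none (N = 0) a single stricter conjunction (rule Z) applies. Conflicting
# accepted calls are then demoted so that the final call set is a strict
# partial matching: no gene appears in two accepted pairs.

#' Competing pairs of a candidate pair
#'
#' All candidate pairs that include either gene of the pair under
#' evaluation, the pair itself excluded.
#'
#' @param candidates a `candidate_table` (or metrics data.frame).
#' @param query_gene,subject_gene the pair under evaluation.
#' @return The competitor rows of `candidates`.
#' @export
competing_pairs <- function(candidates, query_gene, subject_gene) {
  share <- candidates$query_gene_id == query_gene |
    candidates$subject_gene_id == subject_gene
  self <- candidates$query_gene_id == query_gene &
    candidates$subject_gene_id == subject_gene
  out <- candidates[share & !self, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Shared clause: is the pair's protein score the highest among candidate
# pairs for its query gene, or for its subject gene?
.is_top_for_either <- function(pair, competitors) {
  comp_q <- competitors$jaccard_protein[
    competitors$query_gene_id == pair$query_gene_id]
  comp_s <- competitors$jaccard_protein[
    competitors$subject_gene_id == pair$subject_gene_id]
  (!length(comp_q) || pair$jaccard_protein >= max(comp_q)) ||
    (!length(comp_s) || pair$jaccard_protein >= max(comp_s))
}

#' Ortholog decision for a pair with microsynteny support
#'
#' Requires `n_syntenic >= 1`. The pair is accepted when any of the four
#' conditions holds (first match reported as `rule_fired`):
#' \describe{
#'   \item{S1}{no competitor has microsynteny support and the pair's protein
#'     score is greater than or equal to every competitor's.}
#'   \item{S2}{the pair's microsynteny score is at least 2 while no
#'     competitor has microsynteny support.}
#'   \item{S3}{the microsynteny score exceeds every competitor's, the
#'     nucleotide score is greater than or equal to every competitor's, the
#'     protein score exceeds every competitor's by at least 5%
#'     (multiplicative) and is the highest for either the query or the
#'     subject gene.}
#'   \item{S4}{the microsynteny score exceeds every competitor's by at least
#'     2 and the nucleotide score is greater than or equal to every
#'     competitor's.}
#' }
#' Comparisons over an empty competitor set hold vacuously.
#'
#' @param pair one-row data.frame (or list) with `query_gene_id`,
#'   `subject_gene_id`, `jaccard_protein`, `jaccard_nt`, `n_syntenic`.
#' @param competitors data.frame of competing pairs with the same columns.
#' @param config an [ortholog_config()] (supplies the 5% margin and the
#'   synteny margin of S4).
#' @return `list(accepted = logical, rule_fired = "S1".."S4" or "none")`.
#' @export
decide_with_synteny <- function(pair, competitors, config = ortholog_config()) {
  stopifnot(pair$n_syntenic >= 1L)
  n_comp <- nrow(competitors)
  max_n <- if (n_comp) max(competitors$n_syntenic) else -Inf
  max_jp <- if (n_comp) max(competitors$jaccard_protein) else -Inf
  max_jn <- if (n_comp) max(competitors$jaccard_nt) else -Inf
  no_syn_comp <- n_comp == 0L || max_n == 0L

  rule <-
    if (no_syn_comp && pair$jaccard_protein >= max_jp) "S1"
    else if (pair$n_syntenic >= 2L && no_syn_comp) "S2"
    else if (pair$n_syntenic > max_n &&
             pair$jaccard_nt >= max_jn &&
             pair$jaccard_protein >= config$score_margin * max_jp &&
             .is_top_for_either(pair, competitors)) "S3"
    else if (pair$n_syntenic >= max_n + config$synteny_delta &&
             pair$jaccard_nt >= max_jn) "S4"
    else "none"
  list(accepted = rule != "none", rule_fired = rule)
}

#' Ortholog decision for a pair without microsynteny support
#'
#' Requires `n_syntenic = 0`. Stricter criteria apply; the pair is accepted
#' only when all of the following hold (rule `Z`): no competing pair has
#' microsynteny support; the protein alignment covered more than 50% of the
#' longer protein and more than 90% of the shorter protein; both the protein
#' and the nucleotide score exceed every competitor's by at least 5%
#' (multiplicative); and the protein score is the highest for either the
#' query or the subject gene. Competitor comparisons hold vacuously for a
#' lone pair, but the coverage thresholds always apply.
#'
#' @inheritParams decide_with_synteny
#' @return `list(accepted = logical, rule_fired = "Z" or "none")`.
#' @export
decide_without_synteny <- function(pair, competitors, config = ortholog_config()) {
  stopifnot(pair$n_syntenic == 0L)
  n_comp <- nrow(competitors)
  max_n <- if (n_comp) max(competitors$n_syntenic) else 0L
  max_jp <- if (n_comp) max(competitors$jaccard_protein) else -Inf
  max_jn <- if (n_comp) max(competitors$jaccard_nt) else -Inf
  ok <- max_n == 0L &&
    pair$coverage_longer > config$min_coverage_longer &&
    pair$coverage_shorter > config$min_coverage_shorter &&
    pair$jaccard_protein >= config$score_margin * max_jp &&
    pair$jaccard_nt >= config$score_margin * max_jn &&
    .is_top_for_either(pair, competitors)
  list(accepted = ok, rule_fired = if (ok) "Z" else "none")
}

#' Call one-to-one orthologs from a fully scored candidate table
#'
#' Evaluates every candidate pair independently with
#' [decide_with_synteny()] / [decide_without_synteny()] in the context of its
#' competing pairs, then enforces strict one-to-one semantics: when a gene
#' occurs in more than one accepted pair, all of its accepted pairs are
#' demoted to rejected (`rule_fired = "none"`) — ambiguous cases, such as
#' recent identical duplicates, yield no call for any involved gene.
#'
#' @param metrics a candidate table carrying `jaccard_protein`,
#'   `jaccard_nt`, `n_syntenic`, `coverage_longer`, `coverage_shorter` for
#'   every pair.
#' @param query_genome,subject_genome optional [annotated_genome()] objects;
#'   when supplied, output rows are ordered by query gene rank then subject
#'   gene rank (otherwise by gene ids).
#' @param config an [ortholog_config()].
#' @return `metrics` with columns `accepted` (logical) and `rule_fired`
#'   (`"S1"`..`"S4"`, `"Z"`, or `"none"`) appended, deterministically
#'   ordered.
#' @export
call_orthologs <- function(metrics, query_genome = NULL, subject_genome = NULL,
                           config = ortholog_config()) {
  d <- as.data.frame(metrics, stringsAsFactors = FALSE)
  need <- c("query_gene_id", "subject_gene_id", "jaccard_protein",
            "jaccard_nt", "n_syntenic", "coverage_longer", "coverage_shorter")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("metrics missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  n <- nrow(d)
  accepted <- logical(n)
  rule <- character(n)
  for (i in seq_len(n)) {
    comp <- competing_pairs(d, d$query_gene_id[i], d$subject_gene_id[i])
    res <- if (d$n_syntenic[i] >= 1L)
      decide_with_synteny(d[i, ], comp, config)
    else decide_without_synteny(d[i, ], comp, config)
    accepted[i] <- res$accepted
    rule[i] <- res$rule_fired
  }
  # one-to-one enforcement: demote every accepted pair of a conflicted gene
  qn <- table(d$query_gene_id[accepted])
  sn <- table(d$subject_gene_id[accepted])
  conflict <- accepted &
    (d$query_gene_id %in% names(qn)[qn > 1L] |
       d$subject_gene_id %in% names(sn)[sn > 1L])
  accepted[conflict] <- FALSE
  rule[conflict] <- "none"
  d$accepted <- accepted
  d$rule_fired <- rule

  if (!is.null(query_genome) && !is.null(subject_genome)) {
    qg <- query_genome$genes; sg <- subject_genome$genes
    qi <- match(d$query_gene_id, qg$gene_id)
    si <- match(d$subject_gene_id, sg$gene_id)
    o <- order(qg$scaffold_id[qi], qg$rank[qi], sg$scaffold_id[si], sg$rank[si])
  } else {
    o <- order(d$query_gene_id, d$subject_gene_id)
  }
  d <- d[o, , drop = FALSE]
  rownames(d) <- NULL
  d
}
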