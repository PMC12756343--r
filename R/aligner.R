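# Bundled deterministic alignment backends.
#
# Protein: Smith-Waterman local alignment (Biostrings) under a standard
# substitution matrix with affine gaps, plus a raw-score floor that plays the
# role of an E-value cutoff. Nucleotide: a seed-and-extend gap-free HSP
# finder (compiled) emulating a megablast-style search, with greedy selection
# of non-overlapping HSPs. Both are pure functions of their inputs.

.subst_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Self-alignment scores for a set of proteins
#'
#' The self score of a protein is the score of locally aligning it to itself
#' under the configured substitution matrix — the sum of the diagonal
#' substitution scores, since every residue matches itself with a positive
#' score. Self scores are the denominator terms of the modified Jaccard
#' index and use the same scoring parameters as the all-vs-all comparison.
#'
#' @param proteins named character vector of amino-acid sequences.
#' @param config an [ortholog_config()].
#' @return Named numeric vector of self scores, all `> 0`.
#' @export
self_alignment_scores <- function(proteins, config = ortholog_config()) {
  if (any(!nzchar(proteins))) stop("empty protein sequence", call. = FALSE)
  mat <- .subst_matrix(config$protein_matrix)
  diag_score <- diag(mat)
  s <- vapply(proteins, function(p) {
    ch <- strsplit(p, "", fixed = TRUE)[[1L]]
    if (!all(ch %in% names(diag_score)))
      stop("residue outside substitution matrix alphabet: ",
           paste(setdiff(ch, names(diag_score)), collapse = ""), call. = FALSE)
    sum(diag_score[ch])
  }, numeric(1L))
  if (any(s <= 0))
    stop("non-positive self-alignment score; scoring scheme misconfigured",
         call. = FALSE)
  s
}

#' All-vs-all protein comparison
#'
#' Locally aligns every query protein against every subject protein with the
#' bundled deterministic aligner and reports one record per pair whose raw
#' score reaches the configured floor (`protein_score_floor`); pairs below
#' the floor are absent, as they would be under a search tool's E-value
#' cutoff. Coverage fractions are the aligned span over the full protein
#' length, on each side.
#'
#' @param query_proteins,subject_proteins named character vectors of
#'   amino-acid sequences (names are protein/isoform identifiers).
#' @param config an [ortholog_config()].
#' @return data.frame with columns `query_protein_id`, `subject_protein_id`,
#'   `raw_score`, `aligned_query_fraction`, `aligned_subject_fraction`.
#' @export
all_vs_all_protein_scores <- function(query_proteins, subject_proteins,
                                      config = ortholog_config()) {
  if (length(query_proteins) == 0L || length(subject_proteins) == 0L)
    stop("both genomes must provide at least one protein", call. = FALSE)
  mat <- .subst_matrix(config$protein_matrix)
  qs <- Biostrings::AAStringSet(query_proteins)
  ss <- Biostrings::AAStringSet(subject_proteins)
  floor_ <- config$protein_score_floor

  res <- vector("list", length(qs))
  for (i in seq_along(qs)) {
    sc <- Biostrings::pairwiseAlignment(
      ss, qs[[i]], type = "local", substitutionMatrix = mat,
      gapOpening = config$protein_gap_open, gapExtension = config$protein_gap_ext,
      scoreOnly = TRUE)
    keep <- which(sc >= floor_)
    if (!length(keep)) next
    al <- Biostrings::pairwiseAlignment(
      ss[keep], qs[[i]], type = "local", substitutionMatrix = mat,
      gapOpening = config$protein_gap_open, gapExtension = config$protein_gap_ext)
    pat <- Biostrings::pattern(al)   # aligned region on each subject protein
    sub <- Biostrings::subject(al)   # aligned region on the query protein
    res[[i]] <- data.frame(
      query_protein_id = names(qs)[i],
      subject_protein_id = names(ss)[keep],
      raw_score = sc[keep],
      aligned_query_fraction =
        (BiocGenerics::end(sub) - BiocGenerics::start(sub) + 1L) /
          Biostrings::width(qs)[i],
      aligned_subject_fraction =
        (BiocGenerics::end(pat) - BiocGenerics::start(pat) + 1L) /
          Biostrings::width(ss)[keep],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(query_protein_id = character(), subject_protein_id = character(),
                      raw_score = numeric(), aligned_query_fraction = numeric(),
                      aligned_subject_fraction = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Parse a tabular report from an external search tool
#'
#' Adapter contract for external protein or nucleotide search backends:
#' tab-separated text with six columns — query id, subject id, score,
#' alignment length, query length, subject length (the common subset of
#' standard tabular search output). Coverage fractions are derived as
#' alignment length over sequence length, capped at 1.
#'
#' @param path path to the tabular file (no header).
#' @return data.frame in the format of [all_vs_all_protein_scores()].
#' @export
read_alignment_table <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 6L)
    stop("alignment table must have 6 columns: query id, subject id, score, ",
         "alignment length, query length, subject length", call. = FALSE)
  data.frame(
    query_protein_id = as.character(d[[1L]]),
    subject_protein_id = as.character(d[[2L]]),
    raw_score = as.numeric(d[[3L]]),
    aligned_query_fraction = pmin(1, as.numeric(d[[4L]]) / as.numeric(d[[5L]])),
    aligned_subject_fraction = pmin(1, as.numeric(d[[4L]]) / as.numeric(d[[6L]])),
    stringsAsFactors = FALSE)
}

#' Gap-free high-scoring segment pairs between two nucleotide sequences
#'
#' Runs the bundled seed-and-extend backend: exact k-mer seeds extended
#' without gaps under an x-drop rule, scored with match/mismatch values. With
#' `both_strands = TRUE` the reverse complement of `seq_y` is also searched
#' and minus-strand HSP coordinates are mapped back to `seq_y`.
#'
#' @param seq_x,seq_y nucleotide strings.
#' @param config an [ortholog_config()].
#' @param both_strands search both orientations of `seq_y`.
#' @return data.frame of HSPs with 1-based inclusive coordinates: `qstart`,
#'   `qend`, `sstart`, `send`, `score`, `length`, `strand`.
#' @export
nucleotide_hsps <- function(seq_x, seq_y, config = ortholog_config(),
                            both_strands = TRUE) {
  if (!nzchar(seq_x) || !nzchar(seq_y))
    stop("empty nucleotide sequence", call. = FALSE)
  plus <- .nt_hsps_cpp(seq_x, seq_y, config$nt_kmer, config$nt_match,
                       config$nt_mismatch, config$nt_xdrop, config$nt_score_floor)
  plus$strand <- rep("+", nrow(plus))
  out <- plus
  if (both_strands) {
    yrc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_y)))
    minus <- .nt_hsps_cpp(seq_x, yrc, config$nt_kmer, config$nt_match,
                          config$nt_mismatch, config$nt_xdrop, config$nt_score_floor)
    if (nrow(minus)) {
      ny <- nchar(seq_y)
      tmp <- minus$sstart
      minus$sstart <- ny - minus$send + 1L
      minus$send <- ny - tmp + 1L
      minus$strand <- rep("-", nrow(minus))
      out <- rbind(plus, minus)
    }
  }
  out
}

# Greedy selection of non-overlapping HSPs: descending score, ties broken by
# (qstart, sstart, strand); a candidate overlapping an accepted HSP on either
# sequence is discarded.
.select_hsps <- function(hsps) {
  if (nrow(hsps) == 0L) return(hsps)
  hsps <- hsps[order(-hsps$score, hsps$qstart, hsps$sstart, hsps$strand), ,
               drop = FALSE]
  acc <- logical(nrow(hsps))
  for (i in seq_len(nrow(hsps))) {
    j <- which(acc)
    clash <- length(j) > 0L &&
      any(hsps$qstart[i] <= hsps$qend[j] & hsps$qend[i] >= hsps$qstart[j] |
            hsps$sstart[i] <= hsps$send[j] & hsps$send[i] >= hsps$sstart[j])
    acc[i] <- !clash
  }
  hsps[acc, , drop = FALSE]
}

#' Total aligned length between two nucleotide sequences
#'
#' The number of bases in aligned columns over a maximal set of mutually
#' non-overlapping local alignments, selected greedily by descending score
#' from the HSPs of [nucleotide_hsps()]. Deterministic; dissimilar sequences
#' with no HSP above the score floor yield 0.
#'
#' @inheritParams nucleotide_hsps
#' @return Integer aligned length, `0 <= aligned_length <= min(len_x, len_y)`.
#' @export
nucleotide_alignment_length <- function(seq_x, seq_y, config = ortholog_config(),
                                        both_strands = TRUE) {
  sel <- .select_hsps(nucleotide_hsps(seq_x, seq_y, config, both_strands))
  as.integer(sum(sel$length))
}
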