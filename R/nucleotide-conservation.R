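# Nucleotide-level conservation: concatenated exonic sequence of the chosen
# isoform, extended by up to `flank_len` exonic bases per side taken from
# adjacent genes, and compared with the bundled nucleotide backend.

#' Flanked exonic sequence of a gene
#'
#' Builds the nucleotide sequence compared at the conservation step: the
#' spliced exonic sequence of the given isoform (untranslated regions
#' included), extended on both the 5' and 3' ends by up to `flank_len`
#' (default 2000) exonic bases from adjacent genes. Flanks are collected by
#' walking outward in gene-rank order, taking each neighbor's representative
#' (longest-protein) isoform exons concatenated in genomic order, until the
#' target length is gathered or the scaffold is exhausted; intergenic and
#' intronic sequence is never included. When a neighbor overshoots the
#' target, the portion nearest the focal gene is kept. The 5'/3' sides are in
#' the focal gene's transcript orientation: for minus-strand genes the whole
#' construct is reverse-complemented.
#'
#' @param genome an [annotated_genome()].
#' @param gene_id focal gene.
#' @param isoform_id isoform supplying the core sequence; defaults to the
#'   representative isoform.
#' @param flank_len maximum exonic flank per side, in bases.
#' @return List of class `flanked_exonic_seq` with elements `gene_id`,
#'   `isoform_id`, `core_seq`, `flank5`, `flank3`, `full_seq`
#'   (`full_seq == paste0(flank5, core_seq, flank3)`).
#' @export
flanked_exonic_sequence <- function(genome, gene_id, isoform_id = NULL,
                                    flank_len = 2000L) {
  g <- genome$genes[genome$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1L) stop("unknown gene: ", gene_id, call. = FALSE)
  if (is.null(isoform_id)) isoform_id <- representative_isoform(genome, gene_id)
  if (!isoform_id %in% genome$isoforms$isoform_id[genome$isoforms$gene_id == gene_id])
    stop("isoform ", isoform_id, " does not belong to gene ", gene_id,
         call. = FALSE)

  # exonic bases of a locus in genomic (plus-strand) order
  genomic_exonic <- function(gid, iid) {
    e <- genome$exons[genome$exons$isoform_id == iid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    scaf <- genome$seq[[e$scaffold_id[1L]]]
    paste(as.character(
      Biostrings::extractAt(scaf, IRanges::IRanges(e$start + 1L, e$end))),
      collapse = "")
  }

  sc <- g$scaffold_id
  r <- g$rank
  neighbors <- genome$genes[genome$genes$scaffold_id == sc, , drop = FALSE]

  maxr <- max(neighbors$rank)
  gather <- function(side) {
    ranks <- if (side == "left") seq(r - 1L, by = -1L, length.out = r)
    else if (r < maxr) (r + 1L):maxr else integer()
    pieces <- character(); got <- 0L
    for (rr in ranks) {
      if (got >= flank_len) break
      nb <- neighbors$gene_id[neighbors$rank == rr]
      if (!length(nb)) break
      s <- genomic_exonic(nb, representative_isoform(genome, nb))
      pieces <- c(pieces, s)
      got <- got + nchar(s)
    }
    pieces
  }

  left_pieces <- gather("left")    # nearest neighbor first
  right_pieces <- gather("right")
  left <- paste(rev(left_pieces), collapse = "")   # genomic order, far -> near
  right <- paste(right_pieces, collapse = "")
  if (nchar(left) > flank_len)     # keep the side nearest the focal gene
    left <- substring(left, nchar(left) - flank_len + 1L)
  if (nchar(right) > flank_len)
    right <- substring(right, 1L, flank_len)

  core_genomic <- genomic_exonic(gene_id, isoform_id)
  if (g$strand == "-") {
    rc <- function(s) if (nzchar(s))
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))) else ""
    flank5 <- rc(right); flank3 <- rc(left); core <- rc(core_genomic)
  } else {
    flank5 <- left; flank3 <- right; core <- core_genomic
  }
  structure(list(gene_id = gene_id, isoform_id = isoform_id, core_seq = core,
                 flank5 = flank5, flank3 = flank3,
                 full_seq = paste0(flank5, core, flank3)),
            class = "flanked_exonic_seq")
}

#' Modified Jaccard index on aligned nucleotide length
#'
#' `aligned_length / (len_x + len_y - aligned_length)`: the aligned bases
#' over the total compared sequence length not accounted for by the
#' alignment. Lengths are those of the (flanked) sequences actually
#' compared. Vectorized.
#'
#' @param aligned_length bases in aligned columns,
#'   `0 <= aligned_length <= min(len_x, len_y)`.
#' @param len_x,len_y lengths of the two compared sequences.
#' @return Numeric ratio(s) in `[0, 1]`.
#' @export
modified_jaccard_nucleotide <- function(aligned_length, len_x, len_y) {
  if (any(len_x <= 0) || any(len_y <= 0))
    stop("sequence lengths must be positive", call. = FALSE)
  if (any(aligned_length < 0) || any(aligned_length > pmin(len_x, len_y)))
    stop("aligned_length outside [0, min(len_x, len_y)]", call. = FALSE)
  aligned_length / (len_x + len_y - aligned_length)
}

# Compute jaccard_nt for every candidate pair. Flanked sequences are cached
# per (gene, isoform) since several pairs can share a gene.
add_nucleotide_scores <- function(candidates, query_genome, subject_genome,
                                  config = ortholog_config()) {
  if (nrow(candidates) == 0L) {
    candidates$jaccard_nt <- numeric(0)
    return(candidates)
  }
  cache_q <- new.env(parent = emptyenv())
  cache_s <- new.env(parent = emptyenv())
  flank_of <- function(genome, gid, iid, cache) {
    key <- paste(gid, iid, sep = "\r")
    if (is.null(cache[[key]]))
      cache[[key]] <- flanked_exonic_sequence(genome, gid, iid,
                                              config$flank_len)$full_seq
    cache[[key]]
  }
  jn <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    x <- flank_of(query_genome, candidates$query_gene_id[i],
                  candidates$query_isoform_id[i], cache_q)
    y <- flank_of(subject_genome, candidates$subject_gene_id[i],
                  candidates$subject_isoform_id[i], cache_s)
    al <- min(nucleotide_alignment_length(x, y, config),
              nchar(x), nchar(y))
    jn[i] <- modified_jaccard_nucleotide(al, nchar(x), nchar(y))
  }
  candidates$jaccard_nt <- jn
  candidates
}
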