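#' Construct an annotated genome model
#'
#' Assembles the internal genome model used throughout the package: protein
#' coding gene loci with their isoforms and exon structures, plus scaffold
#' sequences. Exon and span coordinates are 0-based half-open; GFF3 input and
#' output converts from/to the 1-based inclusive convention. Gene order on a
#' scaffold (the `rank` column, 0-based) is ascending span start, with ties
#' broken by span end and then gene identifier, and is assigned here.
#'
#' @param genome_id single string naming the genome.
#' @param genes data.frame with columns `gene_id`, `symbol`, `scaffold_id`,
#'   `span_start`, `span_end`, `strand`. Spans may be `NA`, in which case they
#'   are derived from the exons.
#' @param isoforms data.frame with columns `isoform_id`, `gene_id`,
#'   `protein_id`, `protein_seq` (non-empty amino-acid string).
#' @param exons data.frame with columns `isoform_id`, `scaffold_id`, `start`,
#'   `end`, `strand` (0-based half-open).
#' @param seq named [Biostrings::DNAStringSet] of scaffold sequences.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(genome_id, genes, isoforms, exons, seq) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  isoforms <- as.data.frame(isoforms, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  if (nrow(genes) == 0L)
    stop("empty genome: no protein-coding gene loci", call. = FALSE)
  if (!methods::is(seq, "DNAStringSet"))
    seq <- Biostrings::DNAStringSet(unlist(seq))

  # derive spans from exons where not given
  ex_by_gene <- merge(exons, isoforms[, c("isoform_id", "gene_id")],
                      by = "isoform_id")
  sp <- do.call(rbind, lapply(split(ex_by_gene, ex_by_gene$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1L], lo = min(d$start), hi = max(d$end),
               stringsAsFactors = FALSE)
  }))
  m <- match(genes$gene_id, sp$gene_id)
  if (anyNA(m))
    stop("gene(s) without exons: ",
         paste(genes$gene_id[is.na(m)], collapse = ", "), call. = FALSE)
  if (is.null(genes$span_start) || anyNA(genes$span_start)) {
    genes$span_start <- sp$lo[m]
    genes$span_end <- sp$hi[m]
  }
  if (any(genes$span_start > sp$lo[m] | genes$span_end < sp$hi[m]))
    stop("gene span does not cover all exons", call. = FALSE)

  # per-scaffold rank: span_start, then span_end, then gene_id
  genes$rank <- NA_integer_
  for (sc in unique(genes$scaffold_id)) {
    i <- which(genes$scaffold_id == sc)
    o <- order(genes$span_start[i], genes$span_end[i], genes$gene_id[i])
    genes$rank[i[o]] <- seq_along(i) - 1L
  }
  genes <- genes[order(genes$scaffold_id, genes$rank), , drop = FALSE]
  rownames(genes) <- NULL
  rownames(isoforms) <- rownames(exons) <- NULL

  g <- structure(list(genome_id = genome_id, genes = genes,
                      isoforms = isoforms, exons = exons, seq = seq),
                 class = "annotated_genome")
  validate_annotated_genome(g)
  g
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("annotated_genome '%s': %d loci / %d isoforms on %d scaffold(s)\n",
              x$genome_id, nrow(x$genes), nrow(x$isoforms), length(x$seq)))
  invisible(x)
}

# Structural invariants of the model; called on construction and after I/O.
validate_annotated_genome <- function(g) {
  genes <- g$genes; iso <- g$isoforms; ex <- g$exons
  if (!all(genes$scaffold_id %in% names(g$seq)))
    stop("locus scaffold missing from sequence store: ",
         paste(setdiff(genes$scaffold_id, names(g$seq)), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_id", call. = FALSE)
  if (anyDuplicated(iso$isoform_id))
    stop("duplicated isoform_id", call. = FALSE)
  if (!all(iso$gene_id %in% genes$gene_id))
    stop("isoform with unknown gene parent", call. = FALSE)
  if (any(!nzchar(iso$protein_seq)))
    stop("protein-coding isoform with empty protein sequence", call. = FALSE)
  # ranks are a permutation of 0..n-1 per scaffold
  for (sc in unique(genes$scaffold_id)) {
    r <- sort(genes$rank[genes$scaffold_id == sc])
    if (!identical(r, seq_along(r) - 1L))
      stop("ranks on scaffold ", sc, " are not 0..n-1", call. = FALSE)
  }
  slen <- setNames(Biostrings::width(g$seq), names(g$seq))
  for (iid in iso$isoform_id) {
    e <- ex[ex$isoform_id == iid, , drop = FALSE]
    if (nrow(e) == 0L) stop("isoform ", iid, " has no exons", call. = FALSE)
    if (length(unique(e$scaffold_id)) != 1L || length(unique(e$strand)) != 1L)
      stop("isoform ", iid, " spans multiple scaffolds or strands", call. = FALSE)
    if (any(e$start >= e$end)) stop("exon with start >= end in ", iid, call. = FALSE)
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
      stop("overlapping exons in isoform ", iid, call. = FALSE)
    if (max(e$end) > slen[[e$scaffold_id[1L]]])
      stop("exon beyond scaffold end in isoform ", iid, call. = FALSE)
  }
  invisible(g)
}

#' Read an annotated genome from GFF3 + FASTA inputs
#'
#' Parses a gene/mRNA/exon GFF3 hierarchy together with the genome sequence
#' and the protein sequences (FASTA keyed by isoform/mRNA identifier) into an
#' [annotated_genome()]. Only protein-coding loci are retained: an isoform is
#' coding when its identifier has a protein record, and a gene is kept when at
#' least one of its transcripts is coding. The number of dropped non-coding
#' loci is reported with a message.
#'
#' @param gff3_path path to a GFF3 annotation with `ID`/`Parent` links.
#' @param genome_fasta_path path to the genome FASTA (scaffold sequences).
#' @param protein_fasta_path path to the protein FASTA; record identifiers
#'   (first whitespace-delimited token) must match mRNA `ID`s.
#' @param genome_id genome label; defaults to the GFF3 file name stem.
#' @return An `annotated_genome`.
#' @export
read_annotated_genome <- function(gff3_path, genome_fasta_path,
                                  protein_fasta_path,
                                  genome_id = sub("\\.gff3?$", "", basename(gff3_path))) {
  for (p in c(gff3_path, genome_fasta_path, protein_fasta_path))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)

  gr <- rtracklayer::import(gff3_path)
  seq <- Biostrings::readDNAStringSet(genome_fasta_path)
  names(seq) <- sub("\\s.*$", "", names(seq))
  prot <- Biostrings::readAAStringSet(protein_fasta_path)
  names(prot) <- sub("\\s.*$", "", names(prot))

  type <- as.character(gr$type)
  ids <- if (is.null(gr$ID)) rep(NA_character_, length(gr)) else gr$ID
  parent <- if (is.null(gr$Parent)) rep(NA_character_, length(gr)) else
    vapply(gr$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")

  gene_i <- which(type == "gene")
  if (length(gene_i) == 0L) stop("empty genome: GFF3 contains no gene features",
                                 call. = FALSE)
  gene_ids <- ids[gene_i]
  tx_i <- which(!(type %in% c("gene", "exon", "CDS")) & parent %in% gene_ids)
  tx_ids <- ids[tx_i]
  bad_tx <- which(type == "mRNA" & !(parent %in% gene_ids))
  if (length(bad_tx))
    stop("mRNA feature(s) with missing gene parent: ",
         paste(ids[bad_tx], collapse = ", "), call. = FALSE)
  exon_i <- which(type == "exon")
  bad_ex <- exon_i[!(parent[exon_i] %in% tx_ids)]
  if (length(bad_ex))
    stop("exon feature(s) with missing mRNA parent: ",
         paste(ifelse(is.na(ids[bad_ex]), parent[bad_ex], ids[bad_ex]),
               collapse = ", "), call. = FALSE)

  unmatched <- setdiff(names(prot), tx_ids)
  if (length(unmatched))
    stop("protein(s) with no matching annotation: ",
         paste(unmatched, collapse = ", "), call. = FALSE)

  coding_tx <- intersect(tx_ids, names(prot))
  tx_gene <- setNames(parent[tx_i], tx_ids)
  coding_genes <- unique(tx_gene[coding_tx])
  n_dropped <- length(setdiff(gene_ids, coding_genes))
  if (n_dropped > 0L)
    message("dropped ", n_dropped, " non-protein-coding locus/loci")
  if (length(coding_genes) == 0L)
    stop("empty genome: no protein-coding loci after filtering", call. = FALSE)

  gi <- gene_i[gene_ids %in% coding_genes]
  sym <- if (is.null(gr$Name)) rep(NA_character_, length(gr)) else gr$Name
  genes <- data.frame(
    gene_id = ids[gi],
    symbol = ifelse(is.na(sym[gi]), paste0("LOC", ids[gi]), sym[gi]),
    scaffold_id = as.character(GenomeInfoDb::seqnames(gr))[gi],
    span_start = BiocGenerics::start(gr)[gi] - 1L,
    span_end = BiocGenerics::end(gr)[gi],
    strand = as.character(BiocGenerics::strand(gr))[gi],
    stringsAsFactors = FALSE)

  isoforms <- data.frame(
    isoform_id = coding_tx,
    gene_id = unname(tx_gene[coding_tx]),
    protein_id = paste0(coding_tx, ".p"),
    protein_seq = as.character(prot[coding_tx]),
    stringsAsFactors = FALSE)

  keep_ex <- exon_i[parent[exon_i] %in% coding_tx]
  exons <- data.frame(
    isoform_id = parent[keep_ex],
    scaffold_id = as.character(GenomeInfoDb::seqnames(gr))[keep_ex],
    start = BiocGenerics::start(gr)[keep_ex] - 1L,
    end = BiocGenerics::end(gr)[keep_ex],
    strand = as.character(BiocGenerics::strand(gr))[keep_ex],
    stringsAsFactors = FALSE)
  exons <- exons[order(exons$isoform_id, exons$start), , drop = FALSE]

  annotated_genome(genome_id, genes, isoforms, exons, seq)
}

#' Spliced exonic sequence of an isoform
#'
#' Concatenates the genomic sequences of all annotated exons of an isoform —
#' untranslated regions included — in transcript order. Minus-strand isoforms
#' are reverse-complemented, so the result always reads 5' to 3' in the
#' transcript orientation.
#'
#' @param genome an `annotated_genome`.
#' @param isoform_id identifier of an isoform present in the genome.
#' @return A single character string of nucleotides.
#' @export
spliced_exonic_sequence <- function(genome, isoform_id) {
  e <- genome$exons[genome$exons$isoform_id == isoform_id, , drop = FALSE]
  if (nrow(e) == 0L) stop("unknown isoform: ", isoform_id, call. = FALSE)
  e <- e[order(e$start), , drop = FALSE]
  scaf <- genome$seq[[e$scaffold_id[1L]]]
  if (max(e$end) > length(scaf))
    stop("exon beyond scaffold end for isoform ", isoform_id, call. = FALSE)
  parts <- Biostrings::extractAt(scaf, IRanges::IRanges(e$start + 1L, e$end))
  s <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
  if (e$strand[1L] == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

# Representative isoform of a locus: longest protein, ties by isoform_id.
#' Representative isoform of a gene locus
#'
#' The isoform whose protein is longest (ties broken by isoform identifier),
#' used for flank construction and as the default comparison unit.
#'
#' @param genome an `annotated_genome`.
#' @param gene_id a gene identifier.
#' @return The representative `isoform_id`.
#' @export
representative_isoform <- function(genome, gene_id) {
  iso <- genome$isoforms[genome$isoforms$gene_id == gene_id, , drop = FALSE]
  if (nrow(iso) == 0L) stop("unknown gene: ", gene_id, call. = FALSE)
  iso <- iso[order(-nchar(iso$protein_seq), iso$isoform_id), , drop = FALSE]
  iso$isoform_id[1L]
}

#' Write an annotated genome as GFF3 + FASTA fixture files
#'
#' Serializes the model to the three standard inputs accepted by
#' [read_annotated_genome()]: a GFF3 annotation (1-based inclusive), the
#' genome FASTA, and the protein FASTA keyed by isoform identifier. The
#' round trip preserves loci, ranks, and exon coordinates.
#'
#' @param genome an `annotated_genome`.
#' @param out_dir output directory (created if needed).
#' @param prefix file name stem; defaults to the genome id.
#' @return Named character vector of the three file paths.
#' @export
write_genome_fixture <- function(genome, out_dir, prefix = genome$genome_id) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gff <- file.path(out_dir, paste0(prefix, ".gff3"))
  fa <- file.path(out_dir, paste0(prefix, ".fa"))
  pfa <- file.path(out_dir, paste0(prefix, ".proteins.fa"))

  lines <- "##gff-version 3"
  for (gi in seq_len(nrow(genome$genes))) {
    g <- genome$genes[gi, ]
    attr_sym <- if (is.na(g$symbol)) "" else paste0(";Name=", g$symbol)
    lines <- c(lines, sprintf("%s\tsyntolog\tgene\t%d\t%d\t.\t%s\t.\tID=%s%s",
                              g$scaffold_id, g$span_start + 1L, g$span_end,
                              g$strand, g$gene_id, attr_sym))
    iso <- genome$isoforms[genome$isoforms$gene_id == g$gene_id, , drop = FALSE]
    for (ii in seq_len(nrow(iso))) {
      iid <- iso$isoform_id[ii]
      e <- genome$exons[genome$exons$isoform_id == iid, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      lines <- c(lines,
                 sprintf("%s\tsyntolog\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         g$scaffold_id, min(e$start) + 1L, max(e$end),
                         g$strand, iid, g$gene_id),
                 sprintf("%s\tsyntolog\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         e$scaffold_id, e$start + 1L, e$end, e$strand, iid))
    }
  }
  writeLines(lines, gff)
  Biostrings::writeXStringSet(genome$seq, fa)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(genome$isoforms$protein_seq,
                                     genome$isoforms$isoform_id)), pfa)
  c(gff3 = gff, genome_fasta = fa, protein_fasta = pfa)
}
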