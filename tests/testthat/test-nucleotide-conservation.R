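# Deterministic single-exon genomes for flank construction: every gene is a
# plus-strand single exon whose sequence is known, separated by 100 bp of
# spacer, so flank content can be predicted exactly.
flank_fixture <- function(exon_seqs, strands = rep("+", length(exon_seqs))) {
  n <- length(exon_seqs)
  spacer <- strrep("T", 100)
  chunks <- character(); pos <- 0L
  genes <- NULL; isoforms <- NULL; exons <- NULL
  for (i in seq_len(n)) {
    chunks <- c(chunks, spacer); pos <- pos + 100L
    gid <- sprintf("g%02d", i)
    len <- nchar(exon_seqs[i])
    s <- if (strands[i] == "-")
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(exon_seqs[i])))
    else exon_seqs[i]
    chunks <- c(chunks, s)
    genes <- rbind(genes, data.frame(
      gene_id = gid, symbol = gid, scaffold_id = "chr",
      span_start = NA_integer_, span_end = NA_integer_,
      strand = strands[i], stringsAsFactors = FALSE))
    isoforms <- rbind(isoforms, data.frame(
      isoform_id = paste0(gid, ".t1"), gene_id = gid,
      protein_id = paste0(gid, ".p"), protein_seq = "M",
      stringsAsFactors = FALSE))
    exons <- rbind(exons, data.frame(
      isoform_id = paste0(gid, ".t1"), scaffold_id = "chr",
      start = pos, end = pos + len, strand = strands[i],
      stringsAsFactors = FALSE))
    pos <- pos + len
  }
  chunks <- c(chunks, spacer)
  annotated_genome("flankfix", genes, isoforms, exons,
                   Biostrings::DNAStringSet(c(chr = paste(chunks, collapse = ""))))
}

test_that("flanks gather 2 kb of exonic sequence from adjacent genes", {
  g <- flank_fixture(c(rand_dna(2500, seed = 21), rand_dna(1500),
                       rand_dna(2500)))
  f <- flanked_exonic_sequence(g, "g02")
  expect_equal(nchar(f$core_seq), 1500L)
  expect_equal(nchar(f$flank5), 2000L)
  expect_equal(nchar(f$flank3), 2000L)
  expect_equal(nchar(f$full_seq), 5500L)
  expect_equal(f$full_seq, paste0(f$flank5, f$core_seq, f$flank3))
  # content: the 2000 exonic bases nearest the focal gene on each side
  e1 <- spliced_exonic_sequence(g, "g01.t1")
  e3 <- spliced_exonic_sequence(g, "g03.t1")
  expect_equal(f$flank5, substr(e1, 501, 2500))
  expect_equal(f$flank3, substr(e3, 1, 2000))
})

test_that("the first gene on a scaffold has no upstream flank", {
  g <- flank_fixture(c(rand_dna(800, seed = 22), rand_dna(3000)))
  f <- flanked_exonic_sequence(g, "g01")
  expect_equal(nchar(f$flank5), 0L)
  expect_equal(nchar(f$flank3), 2000L)
})

test_that("flanks walk outward across short neighbors", {
  # neighbor offers 300 exonic bases, the next one 5000: flank = 300 + 1700
  g <- flank_fixture(c(rand_dna(5000, seed = 23), rand_dna(300),
                       rand_dna(1000)))
  f <- flanked_exonic_sequence(g, "g03")
  expect_equal(nchar(f$flank5), 2000L)
  e1 <- spliced_exonic_sequence(g, "g01.t1")
  e2 <- spliced_exonic_sequence(g, "g02.t1")
  expect_equal(f$flank5, paste0(substr(e1, 5000 - 1699, 5000), e2))
})

test_that("minus-strand genes yield a transcript-oriented construct", {
  g <- flank_fixture(c(rand_dna(600, seed = 24), rand_dna(500),
                       rand_dna(700)), strands = c("+", "-", "+"))
  f <- flanked_exonic_sequence(g, "g02")
  expect_equal(f$core_seq, spliced_exonic_sequence(g, "g02.t1"))
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  # 5' flank in transcript orientation = RC of the downstream genomic side
  e3_genomic <- spliced_exonic_sequence(g, "g03.t1")  # g03 is plus strand
  expect_equal(f$flank5, rc(e3_genomic))
  expect_equal(f$full_seq, paste0(f$flank5, f$core_seq, f$flank3))
})

test_that("flank truncation holds across a simulated genome", {
  sim <- simulate_genome_pair(simulation_config(n_genes = 15, n_scaffolds = 1,
                                                n_losses = 0, seed = 13))
  g <- sim$query
  exonic_len <- function(gid) {
    iid <- representative_isoform(g, gid)
    e <- g$exons[g$exons$isoform_id == iid, ]
    sum(e$end - e$start)
  }
  for (gid in g$genes$gene_id) {
    f <- flanked_exonic_sequence(g, gid)
    expect_lte(nchar(f$flank5), 2000L)
    expect_lte(nchar(f$flank3), 2000L)
    r <- g$genes$rank[g$genes$gene_id == gid]
    left_avail <- sum(vapply(
      g$genes$gene_id[g$genes$rank < r], exonic_len, numeric(1)))
    if (left_avail >= 2000) {
      side <- if (g$genes$strand[g$genes$gene_id == gid] == "+")
        f$flank5 else f$flank3
      expect_equal(nchar(side), 2000L)
    }
  }
})

test_that("the nucleotide modified Jaccard follows its formula exactly", {
  expect_equal(modified_jaccard_nucleotide(500, 500, 500), 1)
  expect_equal(modified_jaccard_nucleotide(400, 1000, 600), 400 / 1200)
  expect_equal(modified_jaccard_nucleotide(0, 1000, 600), 0)
  expect_error(modified_jaccard_nucleotide(700, 1000, 600), "aligned_length")
})

test_that("a sequence scores jaccard 1 against itself", {
  g <- flank_fixture(c(rand_dna(900, seed = 25), rand_dna(1200)))
  for (gid in c("g01", "g02")) {
    f <- flanked_exonic_sequence(g, gid)
    al <- nucleotide_alignment_length(f$full_seq, f$full_seq)
    expect_equal(modified_jaccard_nucleotide(al, nchar(f$full_seq),
                                             nchar(f$full_seq)), 1)
  }
})
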