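test_that("GFF3 parsing keeps protein-coding loci only and assigns ranks", {
  dir <- withr::local_tempdir()
  fx <- write_mixed_gff_fixture(dir)
  expect_message(
    g <- read_annotated_genome(fx$gff3, fx$genome, fx$proteins),
    "non-protein-coding")
  expect_s3_class(g, "annotated_genome")
  expect_equal(nrow(g$genes), 3L)
  expect_false("ncg" %in% g$genes$gene_id)
  expect_equal(sort(g$genes$rank), 0:2)
  # 1-based inclusive 101..200 becomes 0-based half-open [100, 200)
  e1 <- g$exons[g$exons$isoform_id == "g1.t1", ]
  expect_equal(e1$start, 100L)
  expect_equal(e1$end, 200L)
  expect_equal(e1$end - e1$start, 100L)
})

test_that("a gene with two mRNAs becomes one locus with two isoforms", {
  g <- toy_genome()
  expect_equal(sum(g$isoforms$gene_id == "gA3"), 2L)
  expect_equal(nrow(g$genes[g$genes$gene_id == "gA3", ]), 1L)
  # representative isoform = longest protein
  expect_equal(representative_isoform(g, "gA3"), "gA3.t1")
})

test_that("parse errors are structured and name the offending feature", {
  dir <- withr::local_tempdir()
  fx <- write_mixed_gff_fixture(dir)
  bad <- readLines(fx$gff3)
  bad[3] <- sub("Parent=g1", "Parent=missing", bad[3])
  writeLines(bad, fx$gff3)
  expect_error(read_annotated_genome(fx$gff3, fx$genome, fx$proteins),
               "g1\\.t1")

  fx2 <- write_mixed_gff_fixture(dir)
  writeLines(c(readLines(fx2$proteins), ">orphan", "MXXX"), fx2$proteins)
  expect_error(read_annotated_genome(fx2$gff3, fx2$genome, fx2$proteins),
               "orphan")
})

test_that("an annotation without coding genes is rejected", {
  dir <- withr::local_tempdir()
  fx <- write_mixed_gff_fixture(dir)
  writeLines(character(), fx$proteins)
  expect_error(
    suppressMessages(read_annotated_genome(fx$gff3, fx$genome, fx$proteins)),
    "empty genome")
})

test_that("spliced exonic sequence concatenates exons in transcript order", {
  g <- toy_genome()
  # plus strand, exon lengths 100 + 60
  s <- spliced_exonic_sequence(g, "gA1.t1")
  expect_equal(nchar(s), 160L)
  scaf <- as.character(g$seq[["scfA"]])
  expect_equal(s, paste0(substr(scaf, 101, 200), substr(scaf, 261, 320)))
  # minus strand single exon is reverse-complemented
  m <- spliced_exonic_sequence(g, "gA2.t1")
  fwd <- substr(scaf, 401, 500)
  expect_equal(m, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(fwd))))
})

test_that("minus-strand reverse complement is exact on a tiny fixture", {
  seq <- Biostrings::DNAStringSet(c(s = "TTAACCTT"))
  g <- annotated_genome(
    "rc",
    data.frame(gene_id = "g", symbol = "g", scaffold_id = "s",
               span_start = NA_integer_, span_end = NA_integer_, strand = "-"),
    data.frame(isoform_id = "g.t1", gene_id = "g", protein_id = "p",
               protein_seq = "M"),
    data.frame(isoform_id = "g.t1", scaffold_id = "s", start = 2L, end = 6L,
               strand = "-"),
    seq)
  expect_equal(spliced_exonic_sequence(g, "g.t1"), "GGTT")
})

test_that("spliced length equals the sum of exon lengths for all isoforms", {
  sim <- simulate_genome_pair(simulation_config(n_genes = 15, n_scaffolds = 2,
                                                n_losses = 0, n_inversions = 1,
                                                add_utr = TRUE, seed = 3))
  for (g in list(sim$query, toy_genome())) {
    for (iid in g$isoforms$isoform_id) {
      e <- g$exons[g$exons$isoform_id == iid, ]
      expect_equal(nchar(spliced_exonic_sequence(g, iid)), sum(e$end - e$start))
    }
  }
})

test_that("fixture round trip preserves loci, ranks and exon coordinates", {
  sim <- simulate_genome_pair(simulation_config(n_genes = 12, n_scaffolds = 2,
                                                n_losses = 0, seed = 5))
  g <- sim$query
  dir <- withr::local_tempdir()
  paths <- write_genome_fixture(g, dir)
  g2 <- read_annotated_genome(paths["gff3"], paths["genome_fasta"],
                              paths["protein_fasta"], genome_id = g$genome_id)
  expect_equal(g2$genes[, c("gene_id", "scaffold_id", "span_start",
                            "span_end", "strand", "rank")],
               g$genes[, c("gene_id", "scaffold_id", "span_start",
                           "span_end", "strand", "rank")])
  ord <- function(e) {
    e <- e[order(e$isoform_id, e$start), c("isoform_id", "start", "end")]
    rownames(e) <- NULL
    e
  }
  expect_equal(ord(g2$exons), ord(g$exons))
  expect_setequal(g2$isoforms$isoform_id, g$isoforms$isoform_id)
})

test_that("ranks form a permutation 0..n-1 on every scaffold", {
  sim <- simulate_genome_pair(simulation_config(n_genes = 20, n_scaffolds = 3,
                                                n_losses = 3, seed = 9))
  for (g in list(sim$query, sim$subject)) {
    for (sc in unique(g$genes$scaffold_id)) {
      r <- sort(g$genes$rank[g$genes$scaffold_id == sc])
      expect_equal(r, seq_along(r) - 1L)
    }
  }
})
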