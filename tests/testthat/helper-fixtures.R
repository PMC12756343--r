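# Fixtures are built in code; no data files.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(c("M", sample(aa, n - 1L, replace = TRUE)), collapse = "")
}

# A small two-scaffold genome with known coordinates: three plus/minus genes
# (one with two isoforms) on scfA and one gene on scfB.
toy_genome <- function(genome_id = "toy") {
  seq <- Biostrings::DNAStringSet(c(scfA = rand_dna(1000, seed = 42),
                                    scfB = rand_dna(400)))
  genes <- data.frame(
    gene_id = c("gA1", "gA2", "gA3", "gB1"),
    symbol = c("alpha", "beta", "LOCgA3", "gamma"),
    scaffold_id = c("scfA", "scfA", "scfA", "scfB"),
    span_start = NA_integer_, span_end = NA_integer_,
    strand = c("+", "-", "+", "+"),
    stringsAsFactors = FALSE)
  isoforms <- data.frame(
    isoform_id = c("gA1.t1", "gA2.t1", "gA3.t1", "gA3.t2", "gB1.t1"),
    gene_id = c("gA1", "gA2", "gA3", "gA3", "gB1"),
    protein_id = paste0(c("gA1.t1", "gA2.t1", "gA3.t1", "gA3.t2", "gB1.t1"), ".p"),
    protein_seq = c(rand_protein(50, seed = 1), rand_protein(40),
                    rand_protein(60), rand_protein(45), rand_protein(30)),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    isoform_id = c("gA1.t1", "gA1.t1", "gA2.t1", "gA3.t1", "gA3.t1",
                   "gA3.t2", "gB1.t1"),
    scaffold_id = c(rep("scfA", 6L), "scfB"),
    start = c(100L, 260L, 400L, 600L, 700L, 600L, 50L),
    end = c(200L, 320L, 500L, 660L, 790L, 660L, 250L),
    strand = c("+", "+", "-", "+", "+", "+", "+"),
    stringsAsFactors = FALSE)
  annotated_genome(genome_id, genes, isoforms, exons, seq)
}

# Minimal genome whose loci exist only to carry ranks (single-codon exons),
# used for neighborhood / microsynteny fixtures.
rank_genome <- function(genome_id, n_genes, n_scaffolds = 1L) {
  per <- diff(round(seq(0, n_genes, length.out = n_scaffolds + 1L)))
  genes <- NULL; isoforms <- NULL; exons <- NULL; seqs <- character()
  idx <- 0L
  for (si in seq_len(n_scaffolds)) {
    sc <- sprintf("s%d", si)
    seqs[sc] <- strrep("ATGC", 10L * per[si] + 10L)
    for (i in seq_len(per[si])) {
      idx <- idx + 1L
      gid <- sprintf("%s_g%03d", genome_id, idx)
      genes <- rbind(genes, data.frame(
        gene_id = gid, symbol = gid, scaffold_id = sc,
        span_start = NA_integer_, span_end = NA_integer_, strand = "+",
        stringsAsFactors = FALSE))
      isoforms <- rbind(isoforms, data.frame(
        isoform_id = paste0(gid, ".t1"), gene_id = gid,
        protein_id = paste0(gid, ".p"), protein_seq = "M",
        stringsAsFactors = FALSE))
      exons <- rbind(exons, data.frame(
        isoform_id = paste0(gid, ".t1"), scaffold_id = sc,
        start = 10L * (i - 1L) + 4L, end = 10L * (i - 1L) + 7L, strand = "+",
        stringsAsFactors = FALSE))
    }
  }
  annotated_genome(genome_id, genes, isoforms, exons,
                   Biostrings::DNAStringSet(seqs))
}

# Candidate-table stub carrying only what the synteny/decision code reads.
pair_table <- function(q, s, jp = NULL) {
  d <- data.frame(query_gene_id = q, subject_gene_id = s,
                  stringsAsFactors = FALSE)
  if (!is.null(jp)) d$jaccard_protein <- jp
  d
}

# One fully populated metrics row for decision-rule scenarios.
mk <- function(q = "X", s = "Y", jp = 0.9, jn = 0.5, n = 0L,
               cl = 0.95, cs = 0.95) {
  data.frame(query_gene_id = q, subject_gene_id = s, jaccard_protein = jp,
             jaccard_nt = jn, n_syntenic = as.integer(n),
             coverage_longer = cl, coverage_shorter = cs,
             stringsAsFactors = FALSE)
}

# Independent naive microsynteny oracle: brute-force windows by rank
# arithmetic and one-to-one matching by an explicit double loop.
naive_synteny <- function(qg, sg, qgen, sgen, cand, k = 10L) {
  win <- function(gen, gid) {
    g <- gen$genes[gen$genes$gene_id == gid, ]
    w <- gen$genes[gen$genes$scaffold_id == g$scaffold_id &
                     abs(gen$genes$rank - g$rank) <= k &
                     gen$genes$gene_id != gid, ]
    w[order(w$rank), "gene_id"]
  }
  qn <- win(qgen, qg); sn <- win(sgen, sg)
  key <- paste(cand$query_gene_id, cand$subject_gene_id)
  s_rank <- setNames(sgen$genes$rank, sgen$genes$gene_id)
  used <- rep(FALSE, length(sn))
  n <- 0L
  for (q in qn) {
    best <- NA_integer_
    for (j in seq_along(sn)) {
      if (!used[j] && paste(q, sn[j]) %in% key)
        if (is.na(best) || s_rank[sn[j]] < s_rank[sn[best]]) best <- j
    }
    if (!is.na(best)) { used[best] <- TRUE; n <- n + 1L }
  }
  n
}

# GFF3 text for a 3-coding-gene + 1 ncRNA fixture on one 700 bp scaffold.
write_mixed_gff_fixture <- function(dir) {
  gff <- file.path(dir, "mix.gff3")
  fa <- file.path(dir, "mix.fa")
  pfa <- file.path(dir, "mix.proteins.fa")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t101\t200\t.\t+\t.\tID=g1;Name=one",
    "chr1\ttest\tmRNA\t101\t200\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\ttest\texon\t101\t200\t.\t+\t.\tParent=g1.t1",
    "chr1\ttest\tgene\t251\t400\t.\t-\t.\tID=g2",
    "chr1\ttest\tmRNA\t251\t400\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chr1\ttest\texon\t251\t300\t.\t-\t.\tParent=g2.t1",
    "chr1\ttest\texon\t351\t400\t.\t-\t.\tParent=g2.t1",
    "chr1\ttest\tgene\t451\t500\t.\t+\t.\tID=ncg;Name=ncone",
    "chr1\ttest\tncRNA\t451\t500\t.\t+\t.\tID=ncg.t1;Parent=ncg",
    "chr1\ttest\texon\t451\t500\t.\t+\t.\tParent=ncg.t1",
    "chr1\ttest\tgene\t551\t650\t.\t+\t.\tID=g3;Name=three",
    "chr1\ttest\tmRNA\t551\t650\t.\t+\t.\tID=g3.t1;Parent=g3",
    "chr1\ttest\texon\t551\t650\t.\t+\t.\tParent=g3.t1"), gff)
  writeLines(c(">chr1", rand_dna(700, seed = 11)), fa)
  writeLines(c(">g1.t1", "MKLV", ">g2.t1", "MHEW", ">g3.t1", "MAACD"), pfa)
  list(gff3 = gff, genome = fa, proteins = pfa)
}
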