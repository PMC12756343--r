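test_that("the protein modified Jaccard follows its formula exactly", {
  expect_equal(modified_jaccard_protein(300, 300, 300), 1)
  expect_equal(modified_jaccard_protein(150, 300, 300), 150 / 450)
  expect_equal(modified_jaccard_protein(0, 300, 300), 0)
  expect_error(modified_jaccard_protein(400, 300, 350), "inconsistent")
  expect_error(modified_jaccard_protein(10, 0, 300), "positive")
  # equals 1 iff the pair aligns as well as either self
  expect_lt(modified_jaccard_protein(299, 300, 300), 1)
})

test_that("jaccard is strictly increasing in the cross score", {
  s <- seq(0, 250, by = 25)
  j <- modified_jaccard_protein(s, 250, 300)
  expect_true(all(diff(j) > 0))
})

test_that("best isoform pair maximizes jaccard with lexicographic ties", {
  g <- toy_genome()
  self_q <- setNames(c(300, 200), c("gA3.t1", "gA3.t2"))
  self_s <- setNames(300, "gB1.t1")
  al <- data.frame(
    query_protein_id = c("gA3.t1", "gA3.t2"),
    subject_protein_id = "gB1.t1",
    raw_score = c(270, 100),
    aligned_query_fraction = 1, aligned_subject_fraction = 1,
    stringsAsFactors = FALSE)
  bp <- best_isoform_pair("gA3", "gB1", al, g, g, self_q, self_s)
  expect_equal(bp$query_isoform_id, "gA3.t1")
  expect_equal(bp$jaccard_protein, 270 / (300 + 300 - 270))

  # exact tie on jaccard: (t1, .) and (t2, .) both 0.5 -> t1 wins
  al2 <- al
  al2$raw_score <- c(200, 500 / 3)   # both give jaccard 0.5 with their selves
  bp2 <- best_isoform_pair("gA3", "gB1", al2, g, g, self_q, self_s)
  expect_equal(bp2$query_isoform_id, "gA3.t1")

  expect_null(best_isoform_pair("gA1", "gB1", al, g, g, self_q, self_s))
})

test_that("gene pair scores carry coverage of the longer and shorter protein", {
  g <- toy_genome()
  # gA1 protein is 50 aa, gB1 protein is 30 aa
  self_q <- setNames(250, "gA1.t1")
  self_s <- setNames(150, "gB1.t1")
  al <- data.frame(query_protein_id = "gA1.t1", subject_protein_id = "gB1.t1",
                   raw_score = 120, aligned_query_fraction = 0.55,
                   aligned_subject_fraction = 0.95, stringsAsFactors = FALSE)
  ps <- gene_pair_scores(al, g, g, self_q, self_s)
  expect_equal(ps$coverage_longer, 0.55)
  expect_equal(ps$coverage_shorter, 0.95)
})

test_that("candidate filter keeps pairs within 20% of either gene's best", {
  ps <- pair_table(c("X", "X", "X", "X2"), c("Y1", "Y2", "Y4", "Y4"),
                   jp = c(1.0, 0.85, 0.5, 0.9))
  tab <- candidate_homolog_pairs(ps)
  key <- paste(tab$query_gene_id, tab$subject_gene_id)
  expect_true("X Y1" %in% key)          # best for X
  expect_true("X Y2" %in% key)          # 0.85 >= 0.8 * 1.0
  expect_false("X Y4" %in% key)         # 0.5 < 0.8 and 0.5 < 0.8 * 0.9
  # subject-side rescue: (X, Y3) below X's threshold but best for Y3
  ps2 <- pair_table(c("X", "X"), c("Y1", "Y3"), jp = c(1.0, 0.7))
  tab2 <- candidate_homolog_pairs(ps2)
  expect_true("X Y3" %in% paste(tab2$query_gene_id, tab2$subject_gene_id))
})

test_that("candidate filter equals a brute-force filter on random tables", {
  set.seed(88)
  for (rep in 1:30) {
    nq <- sample(2:10, 1); ns <- sample(2:10, 1)
    m <- matrix(round(runif(nq * ns), 3), nq, ns,
                dimnames = list(paste0("q", 1:nq), paste0("s", 1:ns)))
    keep_pair <- matrix(runif(nq * ns) < 0.5, nq, ns)  # sparse score table
    idx <- which(keep_pair, arr.ind = TRUE)
    if (nrow(idx) == 0L) next
    ps <- pair_table(rownames(m)[idx[, 1]], colnames(m)[idx[, 2]],
                     jp = m[idx])
    got <- candidate_homolog_pairs(ps)
    # oracle: explicit double loop over the sparse matrix
    exp_keys <- character()
    for (r in seq_len(nrow(idx))) {
      q <- rownames(m)[idx[r, 1]]; s <- colnames(m)[idx[r, 2]]
      jq <- ps$jaccard_protein[ps$query_gene_id == q]
      js <- ps$jaccard_protein[ps$subject_gene_id == s]
      if (m[idx[r, 1], idx[r, 2]] >= 0.8 * max(jq) ||
          m[idx[r, 1], idx[r, 2]] >= 0.8 * max(js))
        exp_keys <- c(exp_keys, paste(q, s))
    }
    expect_setequal(paste(got$query_gene_id, got$subject_gene_id), exp_keys)
    # soundness: every gene's best pair survives
    for (q in unique(ps$query_gene_id)) {
      sub <- ps[ps$query_gene_id == q, ]
      best <- sub[which.max(sub$jaccard_protein), ]
      expect_true(paste(best$query_gene_id, best$subject_gene_id) %in%
                    paste(got$query_gene_id, got$subject_gene_id))
    }
  }
})

test_that("the bundled protein backend is symmetric across directions", {
  base <- rand_protein(70, seed = 12)
  tweak <- function(p, i, a) { substr(p, i, i) <- a; p }
  setA <- c(a1 = base, a2 = tweak(base, 15, "G"))
  setB <- c(b1 = tweak(base, 30, "W"), b2 = tweak(base, 50, "P"))
  fwd <- all_vs_all_protein_scores(setA, setB)
  rev <- all_vs_all_protein_scores(setB, setA)
  key_f <- paste(fwd$query_protein_id, fwd$subject_protein_id)
  key_r <- paste(rev$subject_protein_id, rev$query_protein_id)
  expect_setequal(key_f, key_r)
  expect_equal(fwd$raw_score[order(key_f)], rev$raw_score[order(key_r)])
})
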