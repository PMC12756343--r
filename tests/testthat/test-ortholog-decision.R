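test_that("competing pairs are exactly those sharing either gene", {
  tab <- rbind(mk("X", "Y"), mk("X", "Y2"), mk("X2", "Y"), mk("X3", "Y3"))
  comp <- competing_pairs(tab, "X", "Y")
  key <- paste(comp$query_gene_id, comp$subject_gene_id)
  expect_setequal(key, c("X Y2", "X2 Y"))
  expect_equal(nrow(competing_pairs(tab, "X3", "Y3")), 0L)
  tab2 <- rbind(mk("X", "Y"), mk("X", "Y2"), mk("X", "Y3"))
  expect_equal(nrow(competing_pairs(tab2, "X", "Y")), 2L)
})

test_that("decision rules reproduce the hand-evaluated truth table", {
  none <- mk()[0, ]
  scenarios <- list(
    # --- each rule satisfied minimally ---
    list(pair = mk(n = 1), comp = none,
         accepted = TRUE, rule = "S1"),                       # lone syntenic pair
    list(pair = mk(n = 1, jp = 0.8), comp = mk("X", "Y2", jp = 0.8, n = 0),
         accepted = TRUE, rule = "S1"),                       # ties allowed (>=)
    list(pair = mk(n = 2, jp = 0.6), comp = mk("X", "Y2", jp = 0.9, n = 0),
         accepted = TRUE, rule = "S2"),                       # no protein clause
    list(pair = mk(n = 2, jp = 0.9, jn = 0.5),
         comp = mk("X", "Y2", jp = 0.8, jn = 0.5, n = 1),
         accepted = TRUE, rule = "S3"),                       # 0.9 >= 1.05*0.8
    list(pair = mk(n = 3, jp = 0.7, jn = 0.5),
         comp = mk("X", "Y2", jp = 0.9, jn = 0.5, n = 1),
         accepted = TRUE, rule = "S4"),                       # margin of 2 in N
    list(pair = mk(n = 0), comp = none,
         accepted = TRUE, rule = "Z"),                        # lone pair, coverage ok
    # --- each rule defeated by a single clause ---
    list(pair = mk(n = 1, jp = 0.8), comp = mk("X", "Y2", jp = 0.81, n = 0),
         accepted = FALSE, rule = "none"),                    # S1: jp below comp
    list(pair = mk(n = 1, jp = 0.9), comp = mk("X", "Y2", jp = 0.8, n = 1),
         accepted = FALSE, rule = "none"),                    # equal N, no rule
    list(pair = mk(n = 2, jp = 0.9, jn = 0.4),
         comp = mk("X", "Y2", jp = 0.8, jn = 0.5, n = 1),
         accepted = FALSE, rule = "none"),                    # S3: jn below comp
    list(pair = mk(n = 0, cs = 0.85), comp = none,
         accepted = FALSE, rule = "none"),                    # coverage shorter
    list(pair = mk(n = 0, jp = 0.9), comp = mk("X", "Y2", jp = 0.6, n = 1),
         accepted = FALSE, rule = "none"),                    # competitor synteny
    list(pair = mk(n = 0, jp = 0.9, jn = 0.9),
         comp = mk("X", "Y2", jp = 0.9 / 1.04, jn = 0.5, n = 0),
         accepted = FALSE, rule = "none"))                    # 1.04x margin fails
  for (i in seq_along(scenarios)) {
    sc <- scenarios[[i]]
    res <- if (sc$pair$n_syntenic >= 1L)
      decide_with_synteny(sc$pair, sc$comp)
    else decide_without_synteny(sc$pair, sc$comp)
    expect_equal(res$accepted, sc$accepted, label = paste("scenario", i))
    expect_equal(res$rule_fired, sc$rule, label = paste("scenario", i))
  }
})

test_that("the zero-synteny path always enforces coverage thresholds", {
  expect_false(decide_without_synteny(mk(n = 0, cl = 0.5), mk()[0, ])$accepted)
  expect_false(decide_without_synteny(mk(n = 0, cs = 0.9), mk()[0, ])$accepted)
  expect_true(decide_without_synteny(mk(n = 0, cl = 0.51, cs = 0.91),
                                     mk()[0, ])$accepted)
})

test_that("rule preconditions separate the syntenic and zero-synteny paths", {
  expect_error(decide_with_synteny(mk(n = 0), mk()[0, ]))
  expect_error(decide_without_synteny(mk(n = 1), mk()[0, ]))
})

test_that("competing duplicates with equal evidence yield no call at all", {
  # two identical recent duplicates X1, X2 against a single Y
  tab <- rbind(mk("X1", "Y", jp = 0.9, jn = 0.6, n = 3),
               mk("X2", "Y", jp = 0.9, jn = 0.6, n = 3))
  calls <- call_orthologs(tab)
  expect_false(any(calls$accepted))
  expect_true(all(calls$rule_fired == "none"))
})

test_that("ortholog calls form a partial matching on random tables", {
  set.seed(2024)
  for (rep in 1:20) {
    nq <- sample(3:8, 1); ns <- sample(3:8, 1)
    rows <- list()
    for (q in paste0("X", 1:nq)) for (s in paste0("Y", 1:ns))
      if (runif(1) < 0.4)
        rows[[paste(q, s)]] <- mk(q, s, jp = round(runif(1), 2),
                                  jn = round(runif(1), 2),
                                  n = sample(0:4, 1),
                                  cl = runif(1), cs = runif(1))
    if (!length(rows)) next
    calls <- call_orthologs(do.call(rbind, rows))
    acc <- calls[calls$accepted, ]
    expect_false(anyDuplicated(acc$query_gene_id) > 0)
    expect_false(anyDuplicated(acc$subject_gene_id) > 0)
    # rule preconditions: S-rules need N >= 1, Z needs N = 0
    expect_true(all(acc$n_syntenic[acc$rule_fired %in% paste0("S", 1:4)] >= 1))
    expect_true(all(acc$n_syntenic[acc$rule_fired == "Z"] == 0))
  }
})

test_that("calls are deterministic and ordered by gene rank", {
  q <- rank_genome("Q", 6); s <- rank_genome("S", 6)
  tab <- rbind(
    mk(q$genes$gene_id[3], s$genes$gene_id[3], n = 2),
    mk(q$genes$gene_id[1], s$genes$gene_id[1], n = 2))
  c1 <- call_orthologs(tab, q, s)
  c2 <- call_orthologs(tab, q, s)
  expect_identical(c1, c2)
  expect_equal(c1$query_gene_id,
               sort(c(q$genes$gene_id[1], q$genes$gene_id[3])))
  expect_equal(nrow(call_orthologs(mk()[0, ])), 0L)
})
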