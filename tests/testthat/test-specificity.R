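labelled_rep <- function(seed = 1, ...) {
  generate_repertoire(generator_config(...), seed = seed)
}

test_that("neighbour rankings are sorted with input-order tie-breaks", {
  refs <- make_rep(rec(peptide = "P1"), rec(peptide = "P1"),
                   rec(cdr3b = "CASSWWDKGRTDTQYF", peptide = "P2"),
                   ids = c("r1", "r2", "r3"))
  q <- make_rep(rec(), ids = "q1")
  rk <- rank_neighbors(q, refs, "6cdrs")
  r <- rk$q1
  # query identical to r1 and r2: both at distance 0, input order kept
  expect_equal(r$reference[1:2], c("r1", "r2"))
  expect_equal(r$distance[1:2], c(0, 0))
  expect_true(all(diff(r$distance) >= 0))
  expect_error(rank_neighbors(q, refs[0, ]), "empty")
  expect_error(rank_neighbors(refs, refs), "overlap")
})

test_that("rankings equal a brute-force sort of the matrix row", {
  rep <- labelled_rep(seed = 12, n_specificities = 4, n_singletons = 4)
  queries <- as_repertoire(head(as.data.frame(rep), 3))
  refs <- as_repertoire(tail(as.data.frame(rep), nrow(rep) - 3))
  rk <- rank_neighbors(queries, refs, "6cdrs")
  dm <- attr(rk, "distmat")
  for (q in queries$id) {
    d <- dm$normalized[q, refs$id]
    expect_equal(rk[[q]]$reference, refs$id[order(d, seq_along(d))])
  }
})

test_that("top-k success finds duplicated partners and fails singletons", {
  r1 <- rec(peptide = "P1"); r2 <- rec(cdr3b = "CASSWWDKGRTDTQYF",
                                       peptide = "P2")
  dup <- make_rep(r1, r1, r2, r2)
  expect_equal(topk_success(dup, "6cdrs", k = 1)$success, 1.0)
  # all-singleton labels: no query can ever find a partner
  rep <- labelled_rep(seed = 3, n_specificities = 0, n_singletons = 8)
  for (k in c(1, 5)) {
    expect_equal(topk_success(rep, "6cdrs", k = k)$success, 0)
  }
})

test_that("top-k success is monotone in k and matches brute force", {
  rep <- labelled_rep(seed = 14, n_specificities = 5,
                      tcrs_per_specificity = c(4, 4), n_singletons = 0)
  dm <- pairwise_matrix(rep, "6cdrs")
  succ <- sapply(c(1, 2, 5, 10), function(k) {
    topk_success(rep, "6cdrs", k = k, dm = dm)$success
  })
  expect_true(all(diff(succ) >= 0))
  # brute-force k = 1 evaluation
  hits <- sapply(seq_len(nrow(rep)), function(i) {
    d <- dm$normalized[i, -i]
    rep$peptide[-i][which.min(d)] == rep$peptide[i]
  })
  expect_equal(succ[1], mean(hits))
})

test_that("distance thresholds restrict the evaluated queries", {
  rep <- labelled_rep(seed = 15)
  dm <- pairwise_matrix(rep, "6cdrs")
  full <- topk_success(rep, "6cdrs", k = 1, dm = dm)
  thr <- topk_success(rep, "6cdrs", k = 1, threshold = 0.15, dm = dm)
  expect_equal(full$evaluated_fraction, 1)
  expect_lte(thr$evaluated_fraction, 1)
  expect_gte(thr$success, full$success)  # near neighbours are easier
})

test_that("enrichment factor reproduces the published arithmetic", {
  # 45 references, one of the target specificity, found in the top 10
  refs_df <- do.call(rbind, lapply(1:45, function(i) {
    as.data.frame(rec(cdr3b = rand_cdr(14),
                      peptide = sprintf("P%02d", i)),
                  stringsAsFactors = FALSE)
  }))
  refs_df$id <- sprintf("r%02d", 1:45)
  refs <- as_repertoire(refs_df)
  ranking <- data.frame(reference = refs$id, distance = seq(0, 1, length.out = 45),
                        peptide = refs$peptide, mhc = NA)
  expect_equal(enrichment_factor(ranking, "P01", refs, top_n = 10),
               (1 / 10) / (1 / 45))
  expect_equal(enrichment_factor(ranking, "P01", refs, top_n = 10), 4.5)
  # top-10 all of one specificity at reference frequency 1/5
  refs2_df <- refs_df
  refs2_df$peptide <- rep(c("X", "A", "B", "C", "D"), 9)
  refs2 <- as_repertoire(refs2_df)
  rank2 <- data.frame(reference = refs2$id, distance = 0,
                      peptide = c(rep("X", 10), refs2$peptide[11:45]),
                      mhc = NA)
  expect_equal(enrichment_factor(rank2, "X", refs2, top_n = 10), 5)
  # absent from the top n: zero, not an error
  rank3 <- rank2
  rank3$peptide <- c(rep("A", 10), rep("X", 35))
  expect_equal(enrichment_factor(rank3, "X", refs2, top_n = 10), 0)
  expect_error(enrichment_factor(rank2, "ZZZ", refs2), "absent")
  # top-n frequencies over specificities always sum to one
  freqs <- table(head(rank2$peptide, 10)) / 10
  expect_equal(sum(freqs), 1)
})

test_that("share-probability curve reflects cluster structure", {
  # duplicate pairs only: the zero bin has probability one
  r1 <- rec(peptide = "P1"); r2 <- rec(cdr3b = "CASSWWDKGRTDTQYF",
                                       peptide = "P2")
  dup <- make_rep(r1, r1, r2, r2)
  sc <- share_probability_curve(dup, "6cdrs")
  expect_equal(sc$p_share[1], 1)
  expect_true(is.na(sc$p_share[sc$n_pairs == 0][1]))
  # clustered synthetic repertoire: near-zero distances share labels more
  # often than the base rate
  rep <- labelled_rep(seed = 16)
  sc2 <- share_probability_curve(rep, "6cdrs")
  expect_gt(sc2$p_share[1], attr(sc2, "base_rate"))
  expect_error(share_probability_curve(dup[1:2, ], "6cdrs"), "2 distinct")
})

test_that("random labels flatten the share-probability curve", {
  rep <- labelled_rep(seed = 17)
  dm <- pairwise_matrix(rep, "6cdrs")
  set.seed(99)
  diffs <- replicate(10, {
    shuffled <- rep
    shuffled$peptide <- sample(rep$peptide)
    sc <- share_probability_curve(shuffled, "6cdrs", dm = dm)
    occupied <- !is.na(sc$p_share) & sc$n_pairs >= 20
    max(abs(sc$p_share[occupied] - attr(sc, "base_rate")))
  })
  # well-occupied bins hug the base rate once labels are random
  expect_lt(mean(diffs), 0.15)
})

test_that("peptide AUC is perfect for separable clusters, 0.5 when shuffled", {
  rep <- labelled_rep(seed = 18)
  dm <- pairwise_matrix(rep, "6cdrs")
  pa <- peptide_auc(rep, "6cdrs", "PEP01", seed = 4, allow_small = TRUE,
                    dm = dm)
  expect_gt(pa$mean_auc, 0.9)
  expect_error(peptide_auc(rep, "6cdrs", "PEP01", seed = 1), "allow_small")
  # label shuffling destroys the signal
  set.seed(5)
  aucs <- replicate(6, {
    shuffled <- rep
    shuffled$peptide <- sample(rep$peptide)
    peptide_auc(shuffled, "6cdrs", "PEP01", n_splits = 3, seed = 8,
                allow_small = TRUE, dm = dm)$mean_auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("deorphanization calls below the threshold with EF support", {
  rep <- labelled_rep(seed = 19, n_specificities = 4, n_singletons = 2)
  orph <- as_repertoire(transform(head(as.data.frame(rep), 2),
                                  id = c("o1", "o2"), peptide = NA))
  refs <- rep
  calls <- deorphanize(orph, refs, "6cdrs")
  # o1 is identical to a reference: call at distance 0 with its label
  expect_true(calls$called[1])
  expect_equal(calls$distance[1], 0)
  expect_equal(calls$peptide[1], rep$peptide[1])
  expect_gt(calls$ef[1], 1)
  # far orphans yield no call
  far <- make_rep(rec(cdr3a = "CWWWWWWWWWWWWF", cdr3b = "CWWWWWWWWWWWWF",
                      cdr1a = "WWWWWW", cdr2a = "WWWWWWW",
                      cdr1b = "WWWWWW", cdr2b = "WWWWWWW"), ids = "far1")
  calls_far <- deorphanize(far, refs, "6cdrs")
  expect_false(any(calls_far$called))
  expect_true(all(is.na(calls_far$peptide)))
})

test_that("printed lung-patient orphans are recalled against their references", {
  rep <- table4_fixtures()
  tab <- attr(rep, "table4")
  r3 <- tab$id[tab$round == 3]
  orph_ids <- tab$id[tab$round == 3 & tab$role == "orphan"]
  ref_ids <- setdiff(r3, orph_ids)
  orphans <- as_repertoire(as.data.frame(rep[rep$id %in% orph_ids, ]))
  refs_df <- as.data.frame(rep[rep$id %in% ref_ids, ])
  # the reference rows are one repeated receptor; keep unique sequences
  refs_df <- refs_df[!duplicated(refs_df[, c("cdr3a", "cdr3b")]), ]
  refs <- as_repertoire(refs_df)
  calls <- deorphanize(orphans, refs, "6cdrs", call_threshold = 0.15)
  expect_true(all(calls$called))
  expect_true(all(calls$peptide == "DSNDYHILR"))
  # two orphans share an admissible window set with the reference: exact 0
  expect_equal(sort(calls$distance)[1:2], c(0, 0))
  expect_true(all(calls$distance < 0.15))
})
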