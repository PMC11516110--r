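three_leaf <- function() {
  m <- matrix(c(0, 0.2, 0.8,
                0.2, 0, 0.8,
                0.8, 0.8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  m
}

test_that("forced three-leaf topology merges the close pair first", {
  tree <- upgma(three_leaf())
  expect_equal(tree$leaf_order, c("A", "B", "C"))
  expect_equal(tree$coph["A", "B"], 0.2)
  expect_equal(tree$coph["A", "C"], 0.8)
  expect_equal(tree$height, 0.4)
  # ultrametric: root-to-leaf depths all equal
  ph <- tree$phylo
  depths <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-9)
})

test_that("identical records form a zero-length cherry", {
  r <- rec()
  rep <- make_rep(r, r, rec(cdr3b = "CASSWWDKGRTDTQYF"))
  tree <- upgma(pairwise_matrix(rep, "6cdrs"))
  expect_equal(tree$coph["t01", "t02"], 0)
  expect_error(upgma(matrix(NA_real_, 2, 2)), "NA")
})

test_that("cophenetic distances equal the textbook oracle and hclust", {
  set.seed(21)
  for (trial in 1:3) {
    n <- 8
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(n * (n - 1) / 2)
    m <- m + t(m)
    dimnames(m) <- list(letters[1:n], letters[1:n])
    tree <- upgma(m)
    expect_equal(tree$coph, oracle_upgma_coph(m), tolerance = 1e-9)
    hc <- stats::cophenetic(stats::hclust(stats::as.dist(m),
                                          method = "average"))
    expect_equal(tree$coph, as.matrix(hc)[letters[1:n], letters[1:n]],
                 tolerance = 1e-9)
  }
})

test_that("tie-breaking keeps merge order deterministic", {
  # all distances equal: merges must proceed by smallest original indices
  m <- matrix(1, 4, 4); diag(m) <- 0
  dimnames(m) <- list(c("w", "x", "y", "z"), c("w", "x", "y", "z"))
  tree <- upgma(m)
  expect_equal(tree$leaf_order, c("w", "x", "y", "z"))
  expect_true(all(tree$coph[upper.tri(tree$coph)] == 1))
})

test_that("colour changes count circular label switches", {
  tree <- upgma(three_leaf())
  expect_equal(colour_changes(tree, c(A = "p", B = "p", C = "p")), 0L)
  # circular order A,B,C with labels p,p,q: boundaries B|C and C|A
  expect_equal(colour_changes(tree, c(A = "p", B = "p", C = "q")), 2L)
  expect_error(colour_changes(tree, c(A = "p", B = "p")), "unlabelled")
  # a perfectly grouped k-label clustering scores exactly k
  rep <- generate_repertoire(generator_config(n_specificities = 4,
                                              tcrs_per_specificity = c(4, 4),
                                              n_singletons = 0,
                                              substitutions = c(0, 0)),
                             seed = 2)
  dm <- pairwise_matrix(rep, "6cdrs")
  labs <- setNames(rep$peptide, rep$id)
  expect_equal(colour_changes(upgma(dm), labs), 4L)
})

test_that("pMHC-distance averages cophenetic distances per peptide", {
  # three identical TCRs sharing one peptide: 0.00, one block
  r <- rec()
  rep <- make_rep(r, r, r, rec(cdr3b = "CASSWWDKGRTDTQYF"))
  labs <- c(t01 = "P1", t02 = "P1", t03 = "P1", t04 = "P2")
  tree <- upgma(pairwise_matrix(rep, "6cdrs"))
  pm <- pmhc_distance(tree, labs)
  row <- pm$per_peptide[pm$per_peptide$peptide == "P1", ]
  expect_equal(row$pmhc_distance, 0)
  expect_equal(row$n_clusters, 1L)
  expect_equal(pm$overall, 0)  # P2 is a singleton, excluded
  # a single shared-peptide pair contributes its cophenetic distance
  tree3 <- upgma(three_leaf())
  pm3 <- pmhc_distance(tree3, c(A = "p", B = "p", C = "q"))
  expect_equal(pm3$overall, 0.2)
  expect_error(pmhc_distance(tree3, c(A = "p", B = "q", C = "r")),
               ">= 2")
})

test_that("six-leaf pMHC-distance matches hand enumeration", {
  ids <- paste0("L", 1:6)
  m <- matrix(0, 6, 6, dimnames = list(ids, ids))
  set.seed(33)
  m[upper.tri(m)] <- runif(15, 0.1, 1)
  m <- m + t(m)
  tree <- upgma(m)
  labs <- setNames(c("p", "p", "p", "q", "q", "p"), ids)
  pm <- pmhc_distance(tree, labs)
  pp <- names(labs)[labs == "p"]
  hand_p <- mean(tree$coph[pp, pp][upper.tri(diag(4))])
  hand_q <- tree$coph["L4", "L5"]
  expect_equal(pm$overall, mean(c(hand_p, hand_q)), tolerance = 1e-12)
})

test_that("all-equal distances give pMHC-distance equal to that distance", {
  m <- matrix(0.7, 5, 5); diag(m) <- 0
  dimnames(m) <- list(paste0("x", 1:5), paste0("x", 1:5))
  labs <- setNames(c("p", "p", "q", "q", "q"), paste0("x", 1:5))
  pm <- pmhc_distance(upgma(m), labs)
  expect_equal(pm$overall, 0.7, tolerance = 1e-12)
})

test_that("cluster blocks are counted circularly", {
  tree <- upgma(three_leaf())
  labs <- c(A = "p", B = "p", C = "q")
  expect_equal(cluster_count(tree, labs, "p"), 1L)
  expect_equal(cluster_count(tree, labs, "q"), 1L)
  expect_equal(cluster_count(tree, c(A = "p", B = "p", C = "p"), "p"), 1L)
  expect_error(cluster_count(tree, labs, "zzz"), "not on the tree")
  # alternating pattern on a bigger tree, checked by brute force
  ids <- paste0("L", 1:8)
  set.seed(44)
  m <- matrix(0, 8, 8); m[upper.tri(m)] <- runif(28); m <- m + t(m)
  dimnames(m) <- list(ids, ids)
  tr <- upgma(m)
  labs8 <- setNames(rep(c("p", "q"), 4), ids)
  b <- labs8[tr$leaf_order] == "p"
  brute <- sum(b & !c(b[length(b)], b[-length(b)]))
  expect_equal(cluster_count(tr, labs8, "p"), brute)
})

test_that("permutation null is seeded, bounded and add-one corrected", {
  rep <- generate_repertoire(generator_config(n_specificities = 3,
                                              tcrs_per_specificity = c(4, 4),
                                              n_singletons = 2), seed = 6)
  dm <- pairwise_matrix(rep, "6cdrs")
  labs <- setNames(rep$peptide, rep$id)
  pn1 <- permutation_null(dm, labs, "pmhc_distance", B = 100, seed = 17)
  pn2 <- permutation_null(dm, labs, "pmhc_distance", B = 100, seed = 17)
  expect_identical(pn1$null_values, pn2$null_values)
  expect_gt(pn1$p_value, 0)
  expect_lte(pn1$p_value, 1)
  expect_gt(pn1$null_mean, pn1$observed)  # clustered structure beats null
  # a best-possible observed statistic gets the smallest attainable p
  pnc <- permutation_null(dm, labs, "colour_changes", B = 100, seed = 17)
  if (pnc$observed <= min(pnc$null_values)) {
    expect_lte(pnc$p_value, (1 + sum(pnc$null_values == pnc$observed)) / 101)
  }
  expect_error(permutation_null(dm, labs, "pmhc_distance", B = 10), "100")
})
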