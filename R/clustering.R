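# UPGMA dendrograms with pinned tie-breaking, the two clustering-quality
# metrics (colour changes around the circular leaf order, pMHC-distance on
# cophenetic branch lengths), and their permutation nulls.

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomerative clustering producing an ultrametric rooted
#' binary tree. Determinism is pinned: the merged pair is the one with the
#' smallest distance, ties broken by the lexicographically smallest pair of
#' minimal original leaf indices; at each merge the subtree containing the
#' smaller original index is placed on the left, which fixes the
#' left-to-right leaf order.
#'
#' @param dm A `tcr_distmat` (its normalized matrix is used) or a symmetric
#'   numeric matrix with dimnames.
#' @return Object of class `tcr_tree`: list with `phylo` (ape tree),
#'   `leaf_order` (character), `coph` (cophenetic distance matrix: twice
#'   the merge height, i.e. the patristic distance), `newick`, `height`.
#' @export
upgma <- function(dm) {
  D <- if (inherits(dm, "tcr_distmat")) dm$normalized else as.matrix(dm)
  ids <- rownames(D)
  if (is.null(ids)) ids <- colnames(D)
  if (is.null(ids)) ids <- paste0("t", seq_len(nrow(D)))
  n <- nrow(D)
  if (n < 2) stop("need at least 2 leaves", call. = FALSE)
  if (anyNA(D) || any(!is.finite(D))) {
    stop("distance matrix contains NA/non-finite values", call. = FALSE)
  }

  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  heights <- rep(0, n)
  nwk <- ids
  lorder <- as.list(seq_len(n))
  minidx <- seq_len(n)
  active <- rep(TRUE, n)
  work <- D
  coph <- matrix(0, n, n, dimnames = list(ids, ids))
  tol <- 1e-12

  scan <- work
  diag(scan) <- Inf
  for (step in seq_len(n - 1)) {
    bestd <- min(scan)
    cand <- which(scan <= bestd + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographically smallest pair of minimal original leaf indices
    a <- pmin(minidx[cand[, 1]], minidx[cand[, 2]])
    b <- pmax(minidx[cand[, 1]], minidx[cand[, 2]])
    pick <- order(a, b)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    bestd <- work[i, j]
    # left child: subtree containing the smaller original index
    if (minidx[j] < minidx[i]) { tmp <- i; i <- j; j <- tmp }
    h <- bestd / 2
    coph[members[[i]], members[[j]]] <- bestd
    coph[members[[j]], members[[i]]] <- bestd
    nwk[i] <- paste0("(", nwk[i], ":", sprintf("%.12f", h - heights[i]),
                     ",", nwk[j], ":", sprintf("%.12f", h - heights[j]), ")")
    lorder[[i]] <- c(lorder[[i]], lorder[[j]])
    # average-linkage update into slot i
    others <- which(active)
    others <- others[others != i & others != j]
    newd <- (sizes[i] * work[i, others] + sizes[j] * work[j, others]) /
      (sizes[i] + sizes[j])
    work[i, others] <- newd
    work[others, i] <- newd
    scan[i, others] <- newd
    scan[others, i] <- newd
    scan[j, ] <- Inf
    scan[, j] <- Inf
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    heights[i] <- h
    minidx[i] <- min(minidx[i], minidx[j])
    active[j] <- FALSE
  }
  root <- which(active)
  newick <- paste0(nwk[root], ";")
  structure(list(phylo = ape::read.tree(text = newick),
                 leaf_order = ids[lorder[[root]]],
                 coph = coph, newick = newick, height = heights[root]),
            class = "tcr_tree")
}

#' @export
print.tcr_tree <- function(x, ...) {
  cat("<tcr_tree> UPGMA, ", length(x$leaf_order), " leaves, height ",
      format(x$height, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write a tree as Newick
#'
#' @param tree A `tcr_tree` (or `phylo`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ph <- if (inherits(tree, "tcr_tree")) tree$phylo else tree
  ape::write.tree(ph, file = path)
  invisible(path)
}

check_labels <- function(tree, labels) {
  miss <- setdiff(tree$leaf_order, names(labels))
  if (length(miss) > 0) {
    stop("unlabelled leaves: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  labels[tree$leaf_order]
}

#' Colour changes around the dendrogram
#'
#' Number of specificity-label switches between successive leaves in the
#' circular left-to-right leaf order (wrap-around included, matching a
#' circular tree layout read clockwise from the top). Lower values mean
#' better grouping; a perfect grouping of k labels scores exactly k.
#'
#' @param tree A `tcr_tree`.
#' @param labels Named character vector `id -> label` covering every leaf.
#' @return Integer count.
#' @export
colour_changes <- function(tree, labels) {
  lab <- check_labels(tree, labels)
  n <- length(lab)
  if (n < 2) return(0L)
  nxt <- c(lab[-1], lab[1])
  sum(lab != nxt)
}

#' pMHC-distance of a labelled tree
#'
#' For each peptide recognized by at least two TCRs, the mean cophenetic
#' (sum-of-branch-lengths) distance over all its leaf pairs; the overall
#' statistic is the unweighted mean over those peptides, so every peptide
#' contributes equally regardless of how many TCRs recognize it. Singleton
#' peptides are excluded.
#'
#' @inheritParams colour_changes
#' @return List with `overall` and `per_peptide` (data.frame: peptide, n
#'   TCRs, mean distance, number of circular leaf blocks).
#' @export
pmhc_distance <- function(tree, labels) {
  lab <- check_labels(tree, labels)
  peps <- names(table(lab))[table(lab) >= 2]
  if (length(peps) == 0) {
    stop("no peptide is recognized by >= 2 TCRs", call. = FALSE)
  }
  rows <- lapply(peps, function(p) {
    leaves <- names(lab)[lab == p]
    sub <- tree$coph[leaves, leaves]
    data.frame(peptide = p, n = length(leaves),
               pmhc_distance = mean(sub[upper.tri(sub)]),
               n_clusters = cluster_count(tree, labels, p),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  list(overall = mean(per$pmhc_distance), per_peptide = per)
}

#' Number of circular leaf blocks of a peptide
#'
#' Counts the maximal runs of that peptide's leaves in the circular leaf
#' order; a peptide whose leaves sit consecutively forms one block.
#'
#' @inheritParams colour_changes
#' @param peptide Label to count blocks for.
#' @return Integer >= 1 (if the peptide is present).
#' @export
cluster_count <- function(tree, labels, peptide) {
  lab <- check_labels(tree, labels)
  b <- lab == peptide
  if (!any(b)) stop("peptide '", peptide, "' not on the tree", call. = FALSE)
  if (all(b)) return(1L)
  prev <- c(b[length(b)], b[-length(b)])
  sum(b & !prev)
}

#' Permutation null for a clustering statistic
#'
#' Randomly permutes the observed pairwise distances (the condensed vector,
#' reassigned to pairs), rebuilds the UPGMA tree and recomputes the
#' statistic B times. The p-value for these lower-is-better statistics uses
#' the add-one correction: `(1 + #\{null <= observed\}) / (B + 1)`.
#'
#' @param dm `tcr_distmat` or symmetric matrix.
#' @param labels Named labels covering all ids.
#' @param statistic `"pmhc_distance"` or `"colour_changes"`.
#' @param B Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @return List: `observed`, `null_mean`, `null_values`, `p_value`, `B`.
#' @export
permutation_null <- function(dm, labels,
                             statistic = c("pmhc_distance", "colour_changes"),
                             B = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  if (B < 100) stop("B must be >= 100", call. = FALSE)
  D <- if (inherits(dm, "tcr_distmat")) dm$normalized else as.matrix(dm)
  stat_fun <- function(M) {
    tr <- upgma(M)
    if (statistic == "pmhc_distance") pmhc_distance(tr, labels)$overall
    else as.numeric(colour_changes(tr, labels))
  }
  observed <- stat_fun(D)
  n <- nrow(D)
  iu <- upper.tri(D)
  vec <- D[iu]
  null_values <- numeric(B)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (b in seq_len(B)) {
    M <- matrix(0, n, n, dimnames = dimnames(D))
    M[iu] <- sample(vec)
    M <- M + t(M)
    null_values[b] <- stat_fun(M)
  }
  list(observed = observed, null_mean = mean(null_values),
       null_values = null_values,
       p_value = (1 + sum(null_values <= observed)) / (B + 1),
       B = B, statistic = statistic)
}
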