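# Nearest-neighbour specificity prediction: rankings, top-k success,
# enrichment factors, distance-to-probability curves, cross-validated
# per-peptide AUC, and deorphanization calls.

has_label <- function(repertoire) {
  p <- repertoire$peptide
  !is.na(p) & nzchar(p) & tolower(p) != "orphan"
}

#' Rank reference TCRs by distance to each query
#'
#' Computes the pairwise matrix over the combined query + reference set
#' (one shared normalization constant, so distances are comparable across
#' queries) and returns, per query, all references sorted by normalized
#' distance; ties keep the reference input order.
#'
#' @param queries,references `tcr_repertoire` data.frames with disjoint
#'   ids; references must carry peptide labels.
#' @inheritParams tcr_distance
#' @return Named list `query id -> data.frame(reference, distance, peptide,
#'   mhc)`, with the combined `tcr_distmat` as attribute `"distmat"`.
#' @export
rank_neighbors <- function(queries, references,
                           variant = c("6cdrs", "cdr3b", "3d"),
                           weights = NULL, nsesa = NULL,
                           thresholds = default_thresholds(),
                           cdr3_trim = TRUE) {
  variant <- match.arg(variant)
  if (nrow(references) == 0) stop("empty reference set", call. = FALSE)
  if (any(queries$id %in% references$id)) {
    stop("query and reference ids overlap", call. = FALSE)
  }
  combined <- as_repertoire(rbind(as.data.frame(queries),
                                  as.data.frame(references)))
  dm <- pairwise_matrix(combined, variant, weights, nsesa, thresholds,
                        cdr3_trim)
  out <- list()
  for (q in queries$id) {
    d <- dm$normalized[q, references$id]
    ord <- order(d, seq_along(d))
    out[[q]] <- data.frame(reference = references$id[ord],
                           distance = unname(d[ord]),
                           peptide = references$peptide[ord],
                           mhc = references$mhc[ord],
                           stringsAsFactors = FALSE)
  }
  attr(out, "distmat") <- dm
  out
}

#' Leave-one-out top-k specificity success
#'
#' For every labelled TCR, ranks all other labelled TCRs of the repertoire
#' by distance (one shared normalization) and asks whether the true
#' specificity appears among the k nearest. An optional distance threshold
#' restricts evaluation to queries whose nearest neighbour lies strictly
#' below it; the evaluated fraction is reported alongside.
#'
#' @param repertoire Labelled `tcr_repertoire`.
#' @param k Number of nearest neighbours to inspect.
#' @param threshold Optional distance threshold filtering evaluated
#'   queries (strict `<` on the nearest-neighbour distance).
#' @param dm Optional precomputed `tcr_distmat` over the repertoire.
#' @inheritParams tcr_distance
#' @return List: `success` (fraction among evaluated queries),
#'   `evaluated_fraction`, `n_evaluated`, `k`.
#' @export
topk_success <- function(repertoire, variant = c("6cdrs", "cdr3b", "3d"),
                         k = 1, threshold = NULL, weights = NULL,
                         nsesa = NULL, thresholds = default_thresholds(),
                         cdr3_trim = TRUE, dm = NULL) {
  variant <- match.arg(variant)
  lab_ok <- has_label(repertoire)
  rep <- repertoire[lab_ok, , drop = FALSE]
  if (nrow(rep) < 2) stop("need >= 2 labelled TCRs", call. = FALSE)
  if (is.null(dm)) {
    dm <- pairwise_matrix(rep, variant, weights, nsesa, thresholds,
                          cdr3_trim)
  }
  n <- nrow(rep)
  hits <- logical(n)
  nn_dist <- numeric(n)
  for (i in seq_len(n)) {
    d <- dm$normalized[rep$id[i], rep$id[-i]]
    ord <- order(d, seq_along(d))
    nn_dist[i] <- d[ord[1]]
    top <- rep$peptide[-i][ord[seq_len(min(k, n - 1))]]
    hits[i] <- rep$peptide[i] %in% top
  }
  eval_mask <- if (is.null(threshold)) rep(TRUE, n) else nn_dist < threshold
  list(success = if (any(eval_mask)) mean(hits[eval_mask]) else NA_real_,
       evaluated_fraction = mean(eval_mask),
       n_evaluated = sum(eval_mask), k = k)
}

#' Enrichment factor of a specificity in a query's top neighbours
#'
#' Ratio between the frequency of TCRs with the given specificity among
#' the query's `top_n` closest references and their frequency in the whole
#' reference repertoire. A specificity absent from the top `top_n` scores
#' 0; uniform representation scores about 1.
#'
#' @param ranking One query's data.frame from [rank_neighbors()].
#' @param specificity Peptide label.
#' @param references The reference `tcr_repertoire`.
#' @param top_n Neighbourhood size (default 10).
#' @return Non-negative number.
#' @export
enrichment_factor <- function(ranking, specificity, references,
                              top_n = 10) {
  n_ref <- sum(references$peptide == specificity, na.rm = TRUE)
  if (n_ref == 0) {
    stop("specificity '", specificity, "' absent from the references",
         call. = FALSE)
  }
  top <- utils::head(ranking$peptide, top_n)
  (sum(top == specificity) / length(top)) / (n_ref / nrow(references))
}

#' Probability of sharing a pMHC as a function of distance
#'
#' Bins all labelled pairwise distances of a repertoire and reports, per
#' bin, the fraction of pairs whose two TCRs share a peptide. Empty bins
#' are reported with `NA`, not zero. The global base rate (fraction of all
#' pairs sharing a label) rides along as an attribute.
#'
#' @param repertoire Labelled `tcr_repertoire`.
#' @param breaks Bin edges over `[0, 1]` (first bin is closed on both
#'   sides so exact-zero distances are counted).
#' @inheritParams topk_success
#' @return data.frame: `bin_lo`, `bin_hi`, `n_pairs`, `p_share`; attribute
#'   `"base_rate"`.
#' @export
share_probability_curve <- function(repertoire,
                                    variant = c("6cdrs", "cdr3b", "3d"),
                                    breaks = seq(0, 1, by = 0.1),
                                    weights = NULL, nsesa = NULL,
                                    thresholds = default_thresholds(),
                                    cdr3_trim = TRUE, dm = NULL) {
  variant <- match.arg(variant)
  rep <- repertoire[has_label(repertoire), , drop = FALSE]
  if (length(unique(rep$peptide)) < 2) {
    stop("need >= 2 distinct labels", call. = FALSE)
  }
  if (is.null(dm)) {
    dm <- pairwise_matrix(rep, variant, weights, nsesa, thresholds,
                          cdr3_trim)
  }
  iu <- upper.tri(dm$normalized)
  d <- dm$normalized[rep$id, rep$id][iu]
  same <- outer(rep$peptide, rep$peptide, "==")[iu]
  idx <- cut(d, breaks, include.lowest = TRUE, right = FALSE)
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1])
  out$n_pairs <- as.integer(table(idx))
  out$p_share <- as.numeric(tapply(same, idx, mean))
  out$p_share[out$n_pairs == 0] <- NA_real_
  attr(out, "base_rate") <- mean(same)
  out
}

#' Cross-validated nearest-reference AUC for one peptide
#'
#' Repeatedly allocates a fraction of the peptide's TCRs as the reference
#' panel; every remaining TCR of the repertoire is scored by minus its
#' distance to the nearest reference TCR, and the ROC over that score
#' (positives = remaining TCRs of the peptide) gives one AUC per split.
#'
#' @param repertoire Labelled `tcr_repertoire`.
#' @param peptide Peptide whose predictability is assessed; needs at least
#'   `min_tcrs` specific TCRs unless `allow_small`.
#' @param n_splits Number of random splits (default 6).
#' @param reference_fraction Fraction allocated to the reference panel
#'   (default 0.30).
#' @param seed Integer seed.
#' @param min_tcrs Minimum peptide-specific TCRs required (default 20).
#' @param allow_small Lift the `min_tcrs` requirement.
#' @inheritParams topk_success
#' @return List: `mean_auc`, `sd_auc`, `aucs` (per split, NA for skipped
#'   splits).
#' @export
peptide_auc <- function(repertoire, variant = c("6cdrs", "cdr3b", "3d"),
                        peptide, n_splits = 6, reference_fraction = 0.30,
                        seed = 1, min_tcrs = 20, allow_small = FALSE,
                        weights = NULL, nsesa = NULL,
                        thresholds = default_thresholds(),
                        cdr3_trim = TRUE, dm = NULL) {
  variant <- match.arg(variant)
  rep <- repertoire[has_label(repertoire), , drop = FALSE]
  pos_ids <- rep$id[rep$peptide == peptide]
  if (length(pos_ids) < min_tcrs && !allow_small) {
    stop("peptide '", peptide, "' has ", length(pos_ids),
         " TCRs (< ", min_tcrs, "); set allow_small = TRUE to override",
         call. = FALSE)
  }
  if (is.null(dm)) {
    dm <- pairwise_matrix(rep, variant, weights, nsesa, thresholds,
                          cdr3_trim)
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  aucs <- rep(NA_real_, n_splits)
  for (s in seq_len(n_splits)) {
    n_ref <- max(1L, round(reference_fraction * length(pos_ids)))
    ref <- sample(pos_ids, n_ref)
    rest <- setdiff(rep$id, ref)
    is_pos <- rep$peptide[match(rest, rep$id)] == peptide
    if (sum(is_pos) < 2) {
      warning("split ", s, ": fewer than 2 positives, skipped")
      next
    }
    score <- -apply(dm$normalized[rest, ref, drop = FALSE], 1, min)
    roc <- pROC::roc(response = is_pos, predictor = score, quiet = TRUE,
                     levels = c(FALSE, TRUE), direction = "<")
    aucs[s] <- as.numeric(pROC::auc(roc))
  }
  list(mean_auc = mean(aucs, na.rm = TRUE),
       sd_auc = stats::sd(aucs, na.rm = TRUE), aucs = aucs)
}

#' Deorphanize orphan TCRs against a labelled reference set
#'
#' Ranks the references for each orphan (shared normalization across the
#' combined set) and emits a call whenever the nearest-neighbour distance
#' is strictly below `call_threshold` (default 0.15). Each call carries
#' the supporting reference, the enrichment factor of the predicted
#' specificity in the top 10 neighbours, and, when a
#' [share_probability_curve()] is supplied, the probability band of the
#' call's distance bin.
#'
#' @param orphans,references `tcr_repertoire` data.frames.
#' @param call_threshold Strict upper bound on the nearest-neighbour
#'   distance for a call.
#' @param curve Optional output of [share_probability_curve()].
#' @param top_n Neighbourhood size for the enrichment factor.
#' @inheritParams rank_neighbors
#' @return data.frame with one row per orphan: `orphan`, `called`,
#'   `peptide`, `mhc`, `reference`, `distance`, `ef`, `p_share`.
#' @export
deorphanize <- function(orphans, references,
                        variant = c("6cdrs", "cdr3b", "3d"),
                        call_threshold = 0.15, curve = NULL, top_n = 10,
                        weights = NULL, nsesa = NULL,
                        thresholds = default_thresholds(),
                        cdr3_trim = TRUE) {
  variant <- match.arg(variant)
  rk <- rank_neighbors(orphans, references, variant, weights, nsesa,
                       thresholds, cdr3_trim)
  rows <- lapply(orphans$id, function(oid) {
    r <- rk[[oid]]
    nn <- r[1, ]
    called <- nn$distance < call_threshold
    ef <- if (called) {
      enrichment_factor(r, nn$peptide, references, top_n)
    } else NA_real_
    p_share <- NA_real_
    if (called && !is.null(curve)) {
      bin <- which(nn$distance >= curve$bin_lo &
                     (nn$distance < curve$bin_hi |
                        (curve$bin_hi == max(curve$bin_hi) &
                           nn$distance <= curve$bin_hi)))
      if (length(bin) > 0) p_share <- curve$p_share[bin[1]]
    }
    data.frame(orphan = oid, called = called,
               peptide = if (called) nn$peptide else NA_character_,
               mhc = if (called) nn$mhc else NA_character_,
               reference = if (called) nn$reference else NA_character_,
               distance = nn$distance, ef = ef, p_share = p_share,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "rankings") <- rk
  out
}
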