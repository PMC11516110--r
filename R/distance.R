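# The physicochemical TCR distance: Manhattan distance between
# Atchley-factor matrices of 4-mer windows, minimized over window pairs per
# CDR, weighted across loops, and max-normalized over a repertoire.

#' Manhattan distance between two encoded k-mer windows
#'
#' Sum over the k aligned positions of the summed absolute differences of
#' the five Atchley factors. With `normalize = TRUE` the value is divided by
#' k times [max_residue_distance()], the largest attainable distance over
#' the residue alphabet, giving a score in `[0, 1]`.
#'
#' @param a,b Residue strings of equal length.
#' @param normalize Divide by the maximum attainable distance (default TRUE).
#' @return Non-negative number; 0 iff `a == b`.
#' @export
#' @examples
#' fourmer_distance("GYEQ", "GYEQ")
#' fourmer_distance("AAAA", "AAAC", normalize = FALSE)
fourmer_distance <- function(a, b, normalize = TRUE) {
  if (nchar(a) != nchar(b)) {
    stop("windows must have equal length (got ", nchar(a), " and ",
         nchar(b), ")", call. = FALSE)
  }
  d <- sum(abs(encode_residues(a) - encode_residues(b)))
  if (normalize) d <- d / (nchar(a) * max_residue_distance())
  d
}

# Flatten the k-mers of a window_set (re-sliced to width k) into an
# n_windows x (5k) matrix of factor values.
window_matrix <- function(ws, k) {
  wins <- if (k == ws$width) ws$windows else slide_windows(ws$seq, k)
  if (length(wins) == 0) {
    stop("no windows of width ", k, " in ", ws$loop, " ('", ws$seq, "')",
         call. = FALSE)
  }
  t(vapply(wins, function(w) as.numeric(t(encode_residues(w))),
           numeric(5 * k)))
}

#' Distance between two CDR loops
#'
#' The minimum, over all n x m pairs of admissible windows, of the
#' normalized window distance ([fourmer_distance()]). When the two window
#' sets carry different window widths (short loops), both are re-windowed at
#' the shorter width before comparison.
#'
#' @param wa,wb `window_set` objects from [extract_windows()].
#' @return Normalized distance in `[0, 1]`; 0 iff the sets share an
#'   identical admissible window.
#' @export
cdr_distance <- function(wa, wb) {
  stopifnot(inherits(wa, "window_set"), inherits(wb, "window_set"))
  k <- min(wa$width, wb$width)
  ma <- window_matrix(wa, k)
  mb <- window_matrix(wb, k)
  dmin <- Inf
  for (i in seq_len(nrow(ma))) {
    dmin <- min(dmin, min(rowSums(abs(sweep(mb, 2, ma[i, ], "-")))))
  }
  dmin / (k * max_residue_distance())
}

#' CDR weight schemes
#'
#' The published parameterization: 30% per CDR3 and 10% per CDR1/CDR2 for
#' the paired-chain schemes, or all weight on CDR3beta for the single-loop
#' scheme. Weights of the active loops must sum to 1.
#'
#' @param variant `"6cdrs"`, `"3d"` (same weights, nSESA-filtered windows)
#'   or `"cdr3b"`.
#' @return Named numeric vector over [loop_names()].
#' @export
weight_scheme <- function(variant = c("6cdrs", "3d", "cdr3b")) {
  variant <- match.arg(variant)
  if (variant == "cdr3b") {
    w <- c(CDR1a = 0, CDR2a = 0, CDR3a = 0, CDR1b = 0, CDR2b = 0, CDR3b = 1)
  } else {
    w <- c(CDR1a = 0.1, CDR2a = 0.1, CDR3a = 0.3,
           CDR1b = 0.1, CDR2b = 0.1, CDR3b = 0.3)
  }
  w
}

check_weights <- function(weights) {
  if (is.null(names(weights)) || !all(names(weights) %in% loop_names())) {
    stop("weights must be named by CDR loop (",
         paste(loop_names(), collapse = ", "), ")", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  active <- weights[weights > 0]
  if (abs(sum(active) - 1) > 1e-8) {
    stop("active CDR weights must sum to 1 (got ", sum(active), ")",
         call. = FALSE)
  }
  weights
}

# Column name in a repertoire data.frame for a loop name.
loop_column <- function(loop) tolower(loop)

# Window sets for the active loops of one record row.
record_windows <- function(rec, active, variant, nsesa = NULL,
                           thresholds = default_thresholds(),
                           cdr3_trim = TRUE) {
  out <- list()
  for (loop in active) {
    cdr <- rec[[loop_column(loop)]]
    if (is.null(cdr) || is.na(cdr) || !nzchar(cdr)) {
      stop("record '", rec$id, "' is missing loop ", loop, call. = FALSE)
    }
    if (variant == "3d") {
      prof <- nsesa[[rec$id]][[loop]]
      if (is.null(prof)) {
        stop("record '", rec$id, "' has no nSESA profile for loop ", loop,
             call. = FALSE)
      }
      ws <- extract_windows(cdr, loop, "exposed", nsesa = prof,
                            thresholds = thresholds)
    } else {
      is_cdr3 <- loop %in% c("CDR3a", "CDR3b")
      mode <- if (is_cdr3 && cdr3_trim) "cdr3_trimmed" else "full"
      ws <- extract_windows(cdr, loop, mode)
    }
    out[[loop]] <- ws
  }
  out
}

#' Distance between two TCRs
#'
#' Weighted sum over the active CDR loops of the per-loop minimum window
#' distance. The value is the raw (pre-repertoire-normalization) distance in
#' `[0, 1]`; within a repertoire, [pairwise_matrix()] additionally divides
#' by the largest observed pairwise value.
#'
#' @param t1,t2 One-row data.frames (rows of a repertoire).
#' @param variant `"6cdrs"`, `"cdr3b"` or `"3d"`.
#' @param weights Named weights (defaults to [weight_scheme()] of the
#'   variant).
#' @param nsesa For variant `"3d"`: named list `id -> loop -> numeric`.
#' @param thresholds Per-loop exposure thresholds (percent).
#' @param cdr3_trim Apply the first-4/last-3 CDR3 trim in sequence-only
#'   variants (default TRUE).
#' @return Non-negative number; 0 when every active loop pair shares an
#'   identical admissible window.
#' @export
tcr_distance <- function(t1, t2, variant = c("6cdrs", "cdr3b", "3d"),
                         weights = NULL, nsesa = NULL,
                         thresholds = default_thresholds(),
                         cdr3_trim = TRUE) {
  variant <- match.arg(variant)
  if (is.null(weights)) weights <- weight_scheme(variant)
  weights <- check_weights(weights)
  active <- names(weights)[weights > 0]
  w1 <- record_windows(t1, active, variant, nsesa, thresholds, cdr3_trim)
  w2 <- record_windows(t2, active, variant, nsesa, thresholds, cdr3_trim)
  d <- 0
  for (loop in active) {
    d <- d + weights[[loop]] * cdr_distance(w1[[loop]], w2[[loop]])
  }
  d
}

#' Pairwise distance matrix over a repertoire
#'
#' Computes all pairwise TCR distances and normalizes them by the largest
#' calculated distance, so values span `[0, 1]` within the repertoire (all
#' zero when every pair is identical). Identical loop sequences are
#' deduplicated internally; results equal the straight pair-by-pair
#' computation exactly.
#'
#' @inheritParams tcr_distance
#' @param repertoire A repertoire data.frame (see [read_repertoire()]) with
#'   at least 2 rows.
#' @return An object of class `tcr_distmat`: list with `ids`, `raw` and
#'   `normalized` symmetric matrices, `max_raw` (the normalization
#'   constant), and `variant`.
#' @export
pairwise_matrix <- function(repertoire, variant = c("6cdrs", "cdr3b", "3d"),
                            weights = NULL, nsesa = NULL,
                            thresholds = default_thresholds(),
                            cdr3_trim = TRUE) {
  variant <- match.arg(variant)
  if (is.null(weights)) weights <- weight_scheme(variant)
  weights <- check_weights(weights)
  active <- names(weights)[weights > 0]
  n <- nrow(repertoire)
  if (n < 2) stop("need at least 2 records", call. = FALSE)
  ids <- repertoire$id

  raw <- matrix(0, n, n, dimnames = list(ids, ids))
  for (loop in active) {
    wsets <- lapply(seq_len(n), function(i) {
      record_windows(repertoire[i, , drop = FALSE], loop, variant, nsesa,
                     thresholds, cdr3_trim)[[loop]]
    })
    # deduplicate identical admissible strings (3D profiles already folded
    # into the admissible string, so the key is exact)
    keys <- vapply(wsets, function(w) paste(w$seq, w$width), "")
    uniq <- !duplicated(keys)
    uidx <- which(uniq)
    map <- match(keys, keys[uidx])
    m <- length(uidx)
    ud <- matrix(0, m, m)
    if (m > 1) {
      for (i in 1:(m - 1)) for (j in (i + 1):m) {
        ud[i, j] <- ud[j, i] <-
          cdr_distance(wsets[[uidx[i]]], wsets[[uidx[j]]])
      }
    }
    raw <- raw + weights[[loop]] * ud[map, map, drop = FALSE]
  }
  dimnames(raw) <- list(ids, ids)
  diag(raw) <- 0
  max_raw <- max(raw)
  normalized <- if (max_raw > 0) raw / max_raw else raw
  structure(list(ids = ids, raw = raw, normalized = normalized,
                 max_raw = max_raw, variant = variant),
            class = "tcr_distmat")
}

#' @export
print.tcr_distmat <- function(x, ...) {
  cat("<tcr_distmat> ", length(x$ids), " TCRs, variant ", x$variant,
      ", normalization constant ", format(x$max_raw, digits = 4), "\n",
      sep = "")
  invisible(x)
}
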