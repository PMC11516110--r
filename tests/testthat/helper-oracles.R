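# Independent reference implementations used as oracles: straight nested
# loops over substrings for the distance metric, and a textbook UPGMA that
# recomputes cluster averages from the original matrix at every merge.
# These deliberately share no code with the package internals.

# All consecutive k-substrings of s, as a character vector.
oracle_kmers <- function(s, k) {
  if (nchar(s) < k) return(character(0))
  sapply(1:(nchar(s) - k + 1), function(i) substr(s, i, i + k - 1))
}

# Manhattan distance between two equal-length residue strings, by
# position-by-position, factor-by-factor loops.
oracle_window_dist <- function(a, b) {
  at <- atchley_table()
  total <- 0
  for (i in seq_len(nchar(a))) {
    ra <- substr(a, i, i); rb <- substr(b, i, i)
    for (f in 1:5) total <- total + abs(at[ra, f] - at[rb, f])
  }
  total
}

oracle_max_res <- function() {
  at <- atchley_table()
  m <- 0
  for (x in rownames(at)) for (y in rownames(at)) {
    s <- 0
    for (f in 1:5) s <- s + abs(at[x, f] - at[y, f])
    if (s > m) m <- s
  }
  m
}

# Admissible string of a loop under the sequence-only modes, with the
# package's fallback semantics re-derived independently.
oracle_admissible <- function(cdr, trim) {
  if (trim && nchar(cdr) >= 8) {
    sub <- substr(cdr, 5, nchar(cdr) - 3)
    if (nchar(sub) >= 4) return(sub)
  }
  cdr
}

# Min-over-window-pairs normalized CDR distance.
oracle_cdr_dist <- function(sa, sb) {
  k <- min(4, nchar(sa), nchar(sb))
  wa <- oracle_kmers(sa, k); wb <- oracle_kmers(sb, k)
  best <- Inf
  for (a in wa) for (b in wb) {
    best <- min(best, oracle_window_dist(a, b))
  }
  best / (k * oracle_max_res())
}

# Full weighted TCR distance for the sequence-only variants.
oracle_tcr_dist <- function(r1, r2, weights, trim = TRUE) {
  d <- 0
  for (loop in names(weights)) {
    if (weights[[loop]] == 0) next
    col <- tolower(loop)
    is3 <- loop %in% c("CDR3a", "CDR3b")
    sa <- oracle_admissible(r1[[col]], trim && is3)
    sb <- oracle_admissible(r2[[col]], trim && is3)
    d <- d + weights[[loop]] * oracle_cdr_dist(sa, sb)
  }
  d
}

oracle_pairwise <- function(rep, weights, trim = TRUE) {
  n <- nrow(rep)
  m <- matrix(0, n, n, dimnames = list(rep$id, rep$id))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- oracle_tcr_dist(rep[i, ], rep[j, ], weights, trim)
  }
  mx <- max(m)
  list(raw = m, normalized = if (mx > 0) m / mx else m, max_raw = mx)
}

# Textbook UPGMA: clusters as index sets; at each step the pair with the
# smallest average original-matrix distance merges (ties by smallest
# original indices); returns the cophenetic matrix.
oracle_upgma_coph <- function(D) {
  n <- nrow(D)
  clusters <- as.list(1:n)
  coph <- matrix(0, n, n, dimnames = dimnames(D))
  while (length(clusters) > 1) {
    best <- NULL; bestd <- Inf; bestkey <- c(Inf, Inf)
    for (u in 1:(length(clusters) - 1)) for (v in (u + 1):length(clusters)) {
      d <- mean(D[clusters[[u]], clusters[[v]]])
      key <- sort(c(min(clusters[[u]]), min(clusters[[v]])))
      better <- d < bestd - 1e-12 ||
        (abs(d - bestd) <= 1e-12 &&
           (key[1] < bestkey[1] ||
              (key[1] == bestkey[1] && key[2] < bestkey[2])))
      if (better) { bestd <- d; best <- c(u, v); bestkey <- key }
    }
    u <- best[1]; v <- best[2]
    coph[clusters[[u]], clusters[[v]]] <- bestd
    coph[clusters[[v]], clusters[[u]]] <- bestd
    clusters[[u]] <- c(clusters[[u]], clusters[[v]])
    clusters[[v]] <- NULL
  }
  coph
}

# Small repertoire builder for tests: CDR strings given per loop.
make_rep <- function(..., ids = NULL) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  df$id <- ids %||% sprintf("t%02d", seq_len(nrow(df)))
  tcrpcdist::as_repertoire(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A record row with all six loops; defaults give a valid TCR.
rec <- function(cdr3a = "CAVSNTGKLIF", cdr3b = "CASSLGQAYEQYF",
                cdr1a = "TSGFYG", cdr2a = "NVLDGLH",
                cdr1b = "SGHATL", cdr2b = "FQNNGVV", peptide = NA,
                mhc = NA) {
  list(cdr1a = cdr1a, cdr2a = cdr2a, cdr3a = cdr3a,
       cdr1b = cdr1b, cdr2b = cdr2b, cdr3b = cdr3b,
       peptide = peptide, mhc = mhc)
}

# Random CDR string of length n (standard alphabet), C...F framed.
rand_cdr <- function(n) {
  paste0("C", paste(sample(rownames(atchley_table()), n - 2, TRUE),
                    collapse = ""), "F")
}
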