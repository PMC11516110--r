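# Synthetic labelled repertoires: specificity groups grown from seed CDR3
# sequences by controlled substitutions, plus singleton TCRs, with optional
# synthetic nSESA profiles. Emulates the structure of curated TCR sets
# (clusters of biochemically similar receptors sharing a cognate pMHC,
# surrounded by unrelated singletons) without modelling VDJ recombination.

#' Generator configuration
#'
#' Defaults describe the study conditions used throughout the test-suite:
#' 8 specificity groups of 5 TCRs grown from a seed by 2 CDR3
#' substitutions each, plus 10 singletons; CDR3 lengths 12-16; nSESA
#' profiles with 25% buried residues on CDR1/2 and 15% on CDR3.
#'
#' @param n_specificities Number of specificity groups.
#' @param tcrs_per_specificity Integer range `c(lo, hi)` of group sizes.
#' @param n_singletons Number of singleton TCRs (each with a private
#'   label).
#' @param cdr3_length Integer range of seed CDR3 lengths.
#' @param substitutions Integer range of substitutions applied to each
#'   CDR3 chain of a derived TCR.
#' @param vgene_pool Character vector of V-gene names (defaults to the
#'   packaged lookup's genes).
#' @param fraction_buried Named fractions of buried residues for the
#'   synthetic nSESA model: `cdr12` and `cdr3`.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_specificities = 8,
                             tcrs_per_specificity = c(5, 5),
                             n_singletons = 10,
                             cdr3_length = c(12, 16),
                             substitutions = c(2, 2),
                             vgene_pool = NULL,
                             fraction_buried = c(cdr12 = 0.25, cdr3 = 0.15)) {
  cfg <- list(n_specificities = n_specificities,
              tcrs_per_specificity = tcrs_per_specificity,
              n_singletons = n_singletons,
              cdr3_length = cdr3_length,
              substitutions = substitutions,
              vgene_pool = vgene_pool,
              fraction_buried = fraction_buried)
  if (any(unlist(cfg[1:5]) < 0)) stop("counts must be >= 0", call. = FALSE)
  if (max(substitutions) >= min(cdr3_length) - 2) {
    stop("substitutions must fit inside the mutable CDR3 interior",
         call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

rand_int <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1)
}

rand_cdr3 <- function(len) {
  paste0("C", paste(sample(.aa_letters, len - 2, replace = TRUE),
                    collapse = ""), "F")
}

# k substitutions at interior positions (never first/last residue),
# each to a uniformly drawn different residue.
mutate_cdr3 <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  interior <- seq.int(2, length(chars) - 1)
  pos <- sample(interior, k)
  for (p in pos) {
    chars[p] <- sample(setdiff(.aa_letters, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a labelled synthetic repertoire
#'
#' Per specificity group, a seed TCR (random V genes, random CDR3s with
#' conserved C...F termini) and derivatives obtained by substituting the
#' configured number of interior CDR3 residues on each chain; group
#' members share the seed's V genes, hence its CDR1/2. Singletons are
#' drawn independently and each carries a private label. Deterministic
#' under `seed`.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed.
#' @param lookup V-gene lookup used to fill CDR1/2 (defaults to the
#'   packaged synthetic table).
#' @return A labelled `tcr_repertoire`.
#' @export
generate_repertoire <- function(cfg = generator_config(), seed = 1,
                                lookup = read_vgene_lookup()) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  pool <- cfg$vgene_pool %||% names(lookup)
  trav_pool <- grep("^TRAV", pool, value = TRUE)
  trbv_pool <- grep("^TRBV", pool, value = TRUE)
  if (length(trav_pool) == 0 || length(trbv_pool) == 0) {
    stop("vgene_pool must contain TRAV and TRBV genes", call. = FALSE)
  }
  rows <- list()
  add_row <- function(id, trav, trbv, cdr3a, cdr3b, peptide) {
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, patient = "synthetic", trav = trav, traj = "TRAJ0",
      trbv = trbv, trbj = "TRBJ0", cdr3a = cdr3a, cdr3b = cdr3b,
      peptide = peptide, mhc = "HLA-A*02:01", stringsAsFactors = FALSE)
  }
  for (s in seq_len(cfg$n_specificities)) {
    trav <- sample(trav_pool, 1)
    trbv <- sample(trbv_pool, 1)
    ca <- rand_cdr3(rand_int(cfg$cdr3_length))
    cb <- rand_cdr3(rand_int(cfg$cdr3_length))
    pep <- sprintf("PEP%02d", s)
    n_members <- rand_int(cfg$tcrs_per_specificity)
    add_row(sprintf("S%02d_seed", s), trav, trbv, ca, cb, pep)
    for (m in seq_len(max(0, n_members - 1))) {
      k <- rand_int(cfg$substitutions)
      ma <- if (k > 0) mutate_cdr3(ca, k) else ca
      mb <- if (k > 0) mutate_cdr3(cb, k) else cb
      add_row(sprintf("S%02d_%02d", s, m), trav, trbv, ma, mb, pep)
    }
  }
  for (g in seq_len(cfg$n_singletons)) {
    add_row(sprintf("G%02d", g), sample(trav_pool, 1), sample(trbv_pool, 1),
            rand_cdr3(rand_int(cfg$cdr3_length)),
            rand_cdr3(rand_int(cfg$cdr3_length)),
            sprintf("SGL%02d", g))
  }
  df <- do.call(rbind, rows)
  df <- resolve_vgenes(df, lookup)
  if (length(attr(df, "lookup_failures")) > 0) {
    stop("generator V genes missing from the lookup: ",
         paste(names(attr(df, "lookup_failures")), collapse = ", "),
         call. = FALSE)
  }
  as_repertoire(df, name = sprintf("synthetic_seed%d", seed))
}

#' Generate synthetic nSESA profiles for a repertoire
#'
#' Each residue is buried with the configured per-loop-class probability;
#' buried residues draw nSESA uniformly below the loop threshold, exposed
#' residues uniformly above it (offset by 0.5 so strict-threshold
#' comparisons are unambiguous). Deterministic under `seed`.
#'
#' @param repertoire A `tcr_repertoire`.
#' @param cfg A [generator_config()] (its `fraction_buried` is used).
#' @param seed Integer seed.
#' @param thresholds Per-loop thresholds (percent).
#' @return Named list `id -> loop -> numeric`, the [read_nsesa()] shape.
#' @export
generate_nsesa <- function(repertoire, cfg = generator_config(), seed = 1,
                           thresholds = default_thresholds()) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(repertoire))) {
    prof <- list()
    for (loop in loop_names()) {
      cdr <- repertoire[[loop_column(loop)]][i]
      if (is.na(cdr) || !nzchar(cdr)) next
      thr <- thresholds[[loop]]
      frac <- if (grepl("^CDR3", loop)) cfg$fraction_buried[["cdr3"]]
              else cfg$fraction_buried[["cdr12"]]
      n <- nchar(cdr)
      buried <- stats::runif(n) < frac
      v <- numeric(n)
      v[buried] <- stats::runif(sum(buried), 0, thr)
      v[!buried] <- stats::runif(sum(!buried), thr + 0.5, 100)
      prof[[loop]] <- v
    }
    out[[repertoire$id[i]]] <- prof
  }
  out
}

#' The printed deorphanization table as a repertoire
#'
#' Returns the orphan/reference TCR rows of the four experimental
#' deorphanization rounds, with CDR3 sequences and gene names exactly as
#' printed and CDR1/2 resolved from the bundled lookup. The full table
#' (round, pair, role, reported distance and enrichment factor) is
#' attached as attribute `"table4"`.
#'
#' @param lookup V-gene lookup (defaults to the packaged synthetic table).
#' @return A `tcr_repertoire` of 43 records.
#' @export
table4_fixtures <- function(lookup = read_vgene_lookup()) {
  path <- system.file("extdata", "table4_repertoire.tsv",
                      package = "tcrpcdist")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]  # patients contain '#'
  df <- utils::read.delim(text = lines, stringsAsFactors = FALSE,
                          fill = TRUE)
  full <- df
  df <- resolve_vgenes(df, lookup)
  if (length(attr(df, "lookup_failures")) > 0) {
    stop("lookup misses genes: ",
         paste(names(attr(df, "lookup_failures")), collapse = ", "),
         call. = FALSE)
  }
  rep <- as_repertoire(df, name = "table4")
  attr(rep, "table4") <- full
  rep
}
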