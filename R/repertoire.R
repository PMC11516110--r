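# Repertoire, V-gene lookup and nSESA profile I/O. Repertoires are plain
# data.frames (class "tcr_repertoire") with one TCR per row and the columns
# id, patient, trav, traj, trbv, trbj, cdr1a, cdr2a, cdr3a, cdr1b, cdr2b,
# cdr3b, peptide, mhc.

repertoire_columns <- function() {
  c("id", "patient", "trav", "traj", "trbv", "trbj",
    "cdr1a", "cdr2a", "cdr3a", "cdr1b", "cdr2b", "cdr3b",
    "peptide", "mhc")
}

#' Build a repertoire from a data.frame
#'
#' Validates ids (unique, non-empty) and CDR sequences (standard amino
#' acids). Missing optional columns are added as NA. Rows whose present CDR
#' sequences contain non-standard residues are rejected: the Atchley
#' encoding covers only the 20 standard amino acids and no substitution
#' rule is applied.
#'
#' @param df data.frame with at least `id` and `cdr3a`/`cdr3b` (or columns
#'   resolvable via a lookup before calling).
#' @param name Optional repertoire name.
#' @return A `tcr_repertoire` data.frame; rejected rows (with reasons) are
#'   attached as attribute `"rejected"`.
#' @export
as_repertoire <- function(df, name = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in repertoire_columns()) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_character_, nrow(df))
    df[[col]] <- as.character(df[[col]])
  }
  df <- df[, repertoire_columns(), drop = FALSE]
  if (anyNA(df$id) || any(!nzchar(df$id))) {
    stop("every record needs a non-empty id", call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate record ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "),
         call. = FALSE)
  }
  reasons <- character(nrow(df))
  for (loop in loop_names()) {
    col <- loop_column(loop)
    v <- df[[col]]
    bad <- !is.na(v) & nzchar(v) & !is_standard_aa(v)
    reasons[bad] <- paste0(reasons[bad], loop, " has non-standard residues; ")
  }
  rejected <- df[nzchar(reasons), , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- reasons[nzchar(reasons)]
  out <- df[!nzchar(reasons), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("tcr_repertoire", "data.frame"),
            name = name, rejected = rejected)
}

#' Read a V-gene to CDR1/CDR2 lookup table
#'
#' TSV with columns `gene`, `cdr1`, `cdr2` (comment lines `#` allowed).
#' Gene names are normalized by stripping allele suffixes (`*01`) and
#' whitespace; names such as `TRAV14/DV4` are matched verbatim after that
#' normalization. The packaged default
#' (`vgene_cdr_lookup_synthetic.tsv`) is a synthetic stand-in: deterministic
#' placeholder loop sequences, not curated germline data — supply a
#' curated IMGT-derived table for biological use.
#'
#' @param path Path to the TSV; default = the packaged synthetic table.
#' @return Named list `gene -> list(cdr1, cdr2)` with attribute `"species"`.
#' @export
read_vgene_lookup <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vgene_cdr_lookup_synthetic.tsv",
                        package = "tcrpcdist")
  }
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("gene", "cdr1", "cdr2")
  if (!all(need %in% names(df))) {
    stop("lookup table needs columns gene, cdr1, cdr2", call. = FALSE)
  }
  bad <- !is_standard_aa(df$cdr1) | !is_standard_aa(df$cdr2)
  if (any(bad)) {
    stop("non-standard residues in lookup rows: ",
         paste(df$gene[bad], collapse = ", "), call. = FALSE)
  }
  genes <- normalize_gene(df$gene)
  out <- stats::setNames(
    lapply(seq_len(nrow(df)), function(i) list(cdr1 = df$cdr1[i],
                                               cdr2 = df$cdr2[i])),
    genes)
  attr(out, "species") <- "synthetic"
  out
}

# Strip allele suffixes ("*01") and whitespace; uppercase.
normalize_gene <- function(g) {
  toupper(gsub("\\s+", "", sub("\\*.*$", "", g)))
}

#' Fill CDR1/CDR2 from V-gene names
#'
#' For rows whose `cdr1a`/`cdr2a` (resp. `cdr1b`/`cdr2b`) are absent,
#' resolves them from `trav` (resp. `trbv`) via the lookup. Rows with an
#' unresolvable gene and no explicit sequence are rejected with a reason,
#' never dropped silently.
#'
#' @param df Repertoire-shaped data.frame.
#' @param lookup From [read_vgene_lookup()].
#' @return `df` with filled loops; unresolved row reasons in attribute
#'   `"lookup_failures"` (character, named by id).
#' @export
resolve_vgenes <- function(df, lookup) {
  for (col in c("cdr1a", "cdr2a", "cdr1b", "cdr2b")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  fail <- character(0)
  fill <- function(df, gene_col, c1, c2) {
    for (i in seq_len(nrow(df))) {
      missing1 <- is.na(df[[c1]][i]) || !nzchar(df[[c1]][i])
      missing2 <- is.na(df[[c2]][i]) || !nzchar(df[[c2]][i])
      if (!missing1 && !missing2) next
      g <- df[[gene_col]][i]
      if (is.na(g) || !nzchar(g)) {
        fail[[as.character(df$id[i])]] <<-
          paste0("no ", gene_col, " gene and no explicit ", c1, "/", c2)
        next
      }
      hit <- lookup[[normalize_gene(g)]]
      if (is.null(hit)) {
        fail[[as.character(df$id[i])]] <<-
          paste0("unknown V gene '", g, "'")
        next
      }
      if (missing1) df[[c1]][i] <- hit$cdr1
      if (missing2) df[[c2]][i] <- hit$cdr2
    }
    df
  }
  df <- fill(df, "trav", "cdr1a", "cdr2a")
  df <- fill(df, "trbv", "cdr1b", "cdr2b")
  attr(df, "lookup_failures") <- fail
  df
}

#' Read a repertoire TSV
#'
#' Header-ed TSV with one TCR per row (columns as in
#' `repertoire_columns()`; extras are ignored). A missing `cdr3a`+`cdr3b`
#' pair of columns is a hard error. When a lookup is given, absent CDR1/2
#' loops are resolved from the V-gene names; unresolvable rows are moved to
#' the rejection report (attribute `"rejected"`).
#'
#' @param path TSV file.
#' @param lookup Optional [read_vgene_lookup()] result.
#' @param name Optional repertoire name (defaults to the file name).
#' @return A `tcr_repertoire` data.frame.
#' @export
read_repertoire <- function(path, lookup = NULL, name = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#", check.names = TRUE)
  names(df) <- tolower(names(df))
  if (!"cdr3a" %in% names(df) && !"cdr3b" %in% names(df)) {
    stop("repertoire file has no cdr3a/cdr3b column: ", path, call. = FALSE)
  }
  if (!"id" %in% names(df)) df$id <- paste0("tcr", seq_len(nrow(df)))
  if (nrow(df) > 0 && !is.null(lookup)) df <- resolve_vgenes(df, lookup)
  rep <- as_repertoire(df, name = name %||% basename(path))
  fails <- attr(df, "lookup_failures")
  if (length(fails) > 0) {
    keep <- !(rep$id %in% names(fails))
    rej <- attr(rep, "rejected")
    extra <- rep[!keep, , drop = FALSE]
    if (nrow(extra) > 0) {
      extra$reason <- unname(fails[extra$id])
      rej <- rbind(rej, extra)
    }
    rep <- structure(rep[keep, , drop = FALSE],
                     class = c("tcr_repertoire", "data.frame"),
                     name = attr(rep, "name"), rejected = rej)
  }
  rep
}

#' Write a repertoire TSV
#'
#' @param repertoire A `tcr_repertoire`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(repertoire, path) {
  utils::write.table(as.data.frame(repertoire), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read per-residue nSESA profiles
#'
#' TSV with columns `tcr_id`, `loop`, `residue_index`, `residue`,
#' `nsesa_percent`. Values outside `[0, 100]` are hard errors. When a
#' repertoire is supplied, residue letters and profile lengths are
#' cross-checked against its CDR sequences, naming the offending position.
#'
#' @param path TSV file.
#' @param repertoire Optional `tcr_repertoire` to validate against.
#' @return Named list `id -> loop -> numeric vector` (percent).
#' @export
read_nsesa <- function(path, repertoire = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("tcr_id", "loop", "residue_index", "residue", "nsesa_percent")
  if (!all(need %in% names(df))) {
    stop("nSESA file needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$nsesa_percent < 0 | df$nsesa_percent > 100)) {
    bad <- which(df$nsesa_percent < 0 | df$nsesa_percent > 100)[1]
    stop("nSESA value out of [0, 100] at row ", bad, " (",
         df$nsesa_percent[bad], ")", call. = FALSE)
  }
  out <- list()
  for (id in unique(df$tcr_id)) {
    sub <- df[df$tcr_id == id, , drop = FALSE]
    prof <- list()
    for (loop in unique(sub$loop)) {
      ls <- sub[sub$loop == loop, , drop = FALSE]
      ls <- ls[order(ls$residue_index), , drop = FALSE]
      if (!identical(ls$residue_index, seq_len(nrow(ls)))) {
        ls$residue_index <- as.integer(ls$residue_index)
        if (!identical(ls$residue_index, seq_len(nrow(ls)))) {
          stop("nSESA residue_index for ", id, "/", loop,
               " is not 1..n", call. = FALSE)
        }
      }
      if (!is.null(repertoire)) {
        row <- repertoire[repertoire$id == id, , drop = FALSE]
        if (nrow(row) == 1) {
          cdr <- row[[loop_column(loop)]]
          if (!is.na(cdr) && nzchar(cdr)) {
            if (nchar(cdr) != nrow(ls)) {
              stop("nSESA profile length ", nrow(ls), " != ", loop,
                   " length ", nchar(cdr), " for ", id, call. = FALSE)
            }
            seq_res <- strsplit(cdr, "")[[1]]
            mism <- which(seq_res != ls$residue)
            if (length(mism) > 0) {
              stop("nSESA residue mismatch for ", id, "/", loop,
                   " at index ", mism[1], ": profile has '",
                   ls$residue[mism[1]], "', sequence has '",
                   seq_res[mism[1]], "'", call. = FALSE)
            }
          }
        }
      }
      prof[[loop]] <- ls$nsesa_percent
    }
    out[[id]] <- prof
  }
  out
}

#' Write nSESA profiles
#'
#' Inverse of [read_nsesa()]: writes the `tcr_id`/`loop`/`residue_index`/
#' `residue`/`nsesa_percent` TSV. Residue letters are taken from the
#' repertoire sequences.
#'
#' @param profiles Named list `id -> loop -> numeric`.
#' @param repertoire `tcr_repertoire` supplying the sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_nsesa <- function(profiles, repertoire, path) {
  rows <- list()
  for (id in names(profiles)) {
    row <- repertoire[repertoire$id == id, , drop = FALSE]
    for (loop in names(profiles[[id]])) {
      v <- profiles[[id]][[loop]]
      res <- strsplit(row[[loop_column(loop)]], "")[[1]]
      rows[[length(rows) + 1]] <- data.frame(
        tcr_id = id, loop = loop, residue_index = seq_along(v),
        residue = res, nsesa_percent = v, stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a distance matrix TSV
#'
#' Square grid with id header row and column, symmetric with a zero
#' diagonal. The normalization constant and variant ride along as `#`
#' header comments and are restored by [read_distance_matrix()].
#'
#' @param dm A `tcr_distmat` from [pairwise_matrix()].
#' @param path File path.
#' @return `path` (write) or a `tcr_distmat` (read).
#' @export
write_distance_matrix <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# variant=", dm$variant),
               paste0("# max_raw=", format(dm$max_raw, digits = 17))), con)
  writeLines(paste(c("id", dm$ids), collapse = "\t"), con)
  for (i in seq_along(dm$ids)) {
    writeLines(paste(c(dm$ids[i],
                       format(dm$normalized[i, ], digits = 17)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  hdr <- readLines(path)
  meta <- hdr[startsWith(hdr, "#")]
  variant <- sub("^# variant=", "", meta[startsWith(meta, "# variant=")])
  max_raw <- as.numeric(sub("^# max_raw=", "",
                            meta[startsWith(meta, "# max_raw=")]))
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df$id)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(ids, ids)
  structure(list(ids = ids, raw = m * max_raw, normalized = m,
                 max_raw = max_raw,
                 variant = if (length(variant)) variant else NA_character_),
            class = "tcr_distmat")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
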