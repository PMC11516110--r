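# Window extraction: the admissible residue string of a CDR loop under a
# given mode, from which all consecutive k-mers (k = 4 where possible) are
# taken.

#' Extract 4-mer windows from a CDR loop
#'
#' Builds the set of sliding 4-residue windows used by the distance metric.
#' Three modes are supported:
#' \describe{
#'   \item{`full`}{all consecutive 4-mers of the loop;}
#'   \item{`cdr3_trimmed`}{consecutive 4-mers after removing the first four
#'     and last three residues (the conserved junction framework);}
#'   \item{`exposed`}{residues whose nSESA strictly exceeds the loop
#'     threshold are kept in order and consecutive 4-mers are taken over the
#'     filtered string, so windows may span non-consecutive positions of the
#'     original loop.}
#' }
#' If a mode leaves fewer than 4 residues the extraction falls back to the
#' full loop (flagged via `fallback`); loops shorter than 4 residues yield a
#' single window of the loop length, and window widths are reconciled at
#' comparison time by [cdr_distance()].
#'
#' @param cdr Amino-acid string (20 standard letters).
#' @param loop Loop name, one of [loop_names()].
#' @param mode `"full"`, `"cdr3_trimmed"` or `"exposed"`.
#' @param nsesa Numeric vector of per-residue nSESA percents (required for
#'   mode `"exposed"`, same length as `cdr`).
#' @param thresholds Named numeric vector of per-loop exposure thresholds in
#'   percent; defaults to 5 (CDR1/2) and 20 (CDR3).
#' @return An object of class `window_set`: list with elements `loop`,
#'   `mode`, `seq` (admissible residue string), `positions` (1-based source
#'   positions within the loop), `width` (window length), `windows`
#'   (character vector), `fallback` (logical).
#' @export
#' @examples
#' extract_windows("CASSEPGYEQYF", "CDR3b", "cdr3_trimmed")$windows
extract_windows <- function(cdr, loop, mode = c("full", "cdr3_trimmed", "exposed"),
                            nsesa = NULL, thresholds = default_thresholds()) {
  mode <- match.arg(mode)
  if (!is.character(cdr) || length(cdr) != 1 || !nzchar(cdr)) {
    stop("empty CDR sequence for loop ", loop, call. = FALSE)
  }
  if (!is_standard_aa(cdr)) {
    stop("non-standard residues in ", loop, " sequence '", cdr, "'",
         call. = FALSE)
  }
  len <- nchar(cdr)
  fallback <- FALSE
  if (mode == "full") {
    keep <- seq_len(len)
  } else if (mode == "cdr3_trimmed") {
    keep <- if (len >= 8) seq.int(5, len - 3) else integer(0)
  } else {
    if (is.null(nsesa)) {
      stop("mode 'exposed' requires an nSESA profile for ", loop,
           call. = FALSE)
    }
    if (length(nsesa) != len) {
      stop("nSESA length (", length(nsesa), ") does not match ", loop,
           " length (", len, ")", call. = FALSE)
    }
    thr <- thresholds[[loop]]
    keep <- which(nsesa > thr)
  }
  if (length(keep) < 4 && mode != "full") {
    # too few admissible residues: fall back to the whole loop
    keep <- seq_len(len)
    fallback <- TRUE
  }
  sub <- paste(strsplit(cdr, "")[[1]][keep], collapse = "")
  width <- min(4L, length(keep))
  structure(
    list(loop = loop, mode = mode, seq = sub, positions = keep,
         width = width, windows = slide_windows(sub, width),
         fallback = fallback),
    class = "window_set")
}

# All consecutive k-mers of a string (character vector, in order).
slide_windows <- function(seq, k) {
  n <- nchar(seq)
  if (n < k || k < 1) return(character(0))
  vapply(seq_len(n - k + 1), function(i) substr(seq, i, i + k - 1), "")
}

#' @export
print.window_set <- function(x, ...) {
  cat("<window_set> ", x$loop, " [", x$mode,
      if (x$fallback) ", fallback" else "", "] ",
      length(x$windows), " window(s) of width ", x$width, ": ",
      paste(x$windows, collapse = " "), "\n", sep = "")
  invisible(x)
}
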