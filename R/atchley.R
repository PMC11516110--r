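#' @keywords internal
"_PACKAGE"

# Atchley et al. (2005, PNAS 102:6395) factor solution for the 20 standard
# amino acids, published to 3 decimals. Columns: H (polarity/hydrophobicity),
# SS (secondary-structure propensity), SM (size/mass), CD (codon degeneracy),
# ES (electrostatic charge).
.atchley_values <- c(
  # H       SS      SM      CD      ES
  -0.591, -1.302, -0.733,  1.570, -0.146,  # A
  -1.343,  0.465, -0.862, -1.020, -0.255,  # C
   1.050,  0.302, -3.656, -0.259, -3.242,  # D
   1.357, -1.453,  1.477,  0.113, -0.837,  # E
  -1.006, -0.590,  1.891, -0.397,  0.412,  # F
  -0.384,  1.652,  1.330,  1.045,  2.064,  # G
   0.336, -0.417, -1.673, -1.474, -0.078,  # H
  -1.239, -0.547,  2.131,  0.393,  0.816,  # I
   1.831, -0.561,  0.533, -0.277,  1.648,  # K
  -1.019, -0.987, -1.505,  1.266, -0.912,  # L
  -0.663, -1.524,  2.219, -1.005,  1.212,  # M
   0.945,  0.828,  1.299, -0.169,  0.933,  # N
   0.189,  2.081, -1.628,  0.421, -1.392,  # P
   0.931, -0.179, -3.005, -0.503, -1.853,  # Q
   1.538, -0.055,  1.502,  0.440,  2.897,  # R
  -0.228,  1.399, -4.760,  0.670, -2.647,  # S
  -0.032,  0.326,  2.213,  0.908,  1.313,  # T
  -1.337, -0.279, -0.544,  1.242, -1.262,  # V
  -0.595,  0.009,  0.672, -2.128, -0.184,  # W
   0.260,  0.830,  3.097, -0.838,  1.512   # Y
)

.aa_letters <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.pkg_env <- new.env(parent = emptyenv())

#' Atchley factor table
#'
#' Returns the five published Atchley factors for each of the 20 standard
#' amino acids as a 20 x 5 numeric matrix. Rows are named by one-letter
#' residue codes; columns are `H` (polarity/hydrophobicity), `SS`
#' (secondary-structure propensity), `SM` (size/mass), `CD` (codon
#' degeneracy) and `ES` (electrostatic charge). The table is the fixed
#' encoding used throughout the distance metric and is never modified at
#' run time.
#'
#' @return A 20 x 5 numeric matrix with row names `A`..`Y`.
#' @export
#' @examples
#' atchley_table()["A", ]
atchley_table <- function() {
  if (is.null(.pkg_env$atchley)) {
    m <- matrix(.atchley_values, nrow = 20, ncol = 5, byrow = TRUE,
                dimnames = list(.aa_letters, c("H", "SS", "SM", "CD", "ES")))
    .pkg_env$atchley <- m
  }
  .pkg_env$atchley
}

#' Largest single-residue Atchley distance
#'
#' The maximum over all residue pairs of the summed absolute factor
#' differences. Multiplying by the window length k gives the largest
#' attainable Manhattan distance between two k-mer factor matrices, the
#' constant used to normalize per-window distances into `[0, 1]`.
#'
#' @return A single positive number.
#' @export
max_residue_distance <- function() {
  if (is.null(.pkg_env$max_res_dist)) {
    at <- atchley_table()
    m <- 0
    for (i in 1:19) for (j in (i + 1):20) {
      m <- max(m, sum(abs(at[i, ] - at[j, ])))
    }
    .pkg_env$max_res_dist <- m
  }
  .pkg_env$max_res_dist
}

# Encode a residue string as an nchar x 5 matrix of Atchley factors.
# Errors on any letter outside the 20-residue alphabet.
encode_residues <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, .aa_letters)
  if (length(bad) > 0) {
    stop("non-standard residue(s) ", paste(unique(bad), collapse = ", "),
         " in sequence '", seq, "'", call. = FALSE)
  }
  atchley_table()[chars, , drop = FALSE]
}

# TRUE when every character of x is a standard amino-acid letter.
is_standard_aa <- function(x) {
  nzchar(x) & !grepl(paste0("[^", paste(.aa_letters, collapse = ""), "]"), x)
}

#' Canonical CDR loop names
#'
#' @return Character vector of the six loop names in fixed order.
#' @export
loop_names <- function() {
  c("CDR1a", "CDR2a", "CDR3a", "CDR1b", "CDR2b", "CDR3b")
}

# Default exposure thresholds (percent nSESA, strict >): germline loops 5,
# junctional CDR3 loops 20.
default_thresholds <- function() {
  c(CDR1a = 5, CDR2a = 5, CDR3a = 20, CDR1b = 5, CDR2b = 5, CDR3b = 20)
}
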