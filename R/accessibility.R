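# Solvent accessibility: a Shrake-Rupley solvent-probe surface computation
# over PDB structures, normalized per residue by its reference area in a
# Gly-X-Gly tripeptide to give nSESA in percent.

# Tien et al. (2013, PLoS ONE 8:e80635) theoretical maximum accessible
# surface areas (A^2), Gly-X-Gly reference state.
.ref_areas <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)

#' Gly-X-Gly reference surface areas
#'
#' Published theoretical maximum accessible surface areas per residue type
#' (square Angstroms) in an extended Gly-X-Gly tripeptide, used to
#' normalize residue surface areas into nSESA percentages.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
reference_areas <- function() .ref_areas

# van der Waals radii (A) by element, Bondi-style values.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                H = 1.20, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

# Deterministic quasi-uniform points on the unit sphere (golden-section
# spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom accessible surface area with a rolling solvent probe: each
#' atom's expanded sphere (van der Waals radius + probe radius) is sampled
#' with a deterministic quasi-uniform point set, and the accessible
#' fraction is the share of points outside every other atom's expanded
#' sphere.
#'
#' @param xyz Numeric n x 3 coordinate matrix (Angstroms).
#' @param elements Character vector of element symbols (length n).
#' @param probe Probe radius in Angstroms (default 1.4, water).
#' @param n_points Sphere sample points per atom (default 480).
#' @return Numeric vector of per-atom areas (square Angstroms).
#' @export
shrake_rupley <- function(xyz, elements, probe = 1.4, n_points = 480) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(elements))
  radii <- .vdw_radii[toupper(elements)]
  radii[is.na(radii)] <- 1.70
  n <- nrow(xyz)
  pts <- fibonacci_sphere(n_points)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ri <- radii[i] + probe
    # neighbours whose expanded spheres can clip atom i's sphere
    dd <- sqrt(rowSums((xyz - matrix(xyz[i, ], n, 3, byrow = TRUE))^2))
    nb <- which(dd < ri + radii + probe & seq_len(n) != i)
    sp <- pts * ri + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      rj <- radii[j] + probe
      d2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      acc <- acc & d2 > rj^2
      if (!any(acc)) break
    }
    out[i] <- mean(acc) * 4 * pi * ri^2
  }
  out
}

#' Read CDR residue ranges
#'
#' Sidecar describing where each CDR loop sits in a structure: columns /
#' fields `loop`, `chain`, `start`, `end` (PDB residue numbers, 1-based,
#' inclusive). Accepts a TSV or a JSON array of objects.
#'
#' @param path File path (`.json` or TSV).
#' @return data.frame with columns loop, chain, start, end.
#' @export
read_cdr_ranges <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::fromJSON(path))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            comment.char = "#")
  }
  need <- c("loop", "chain", "start", "end")
  if (!all(need %in% names(df))) {
    stop("CDR ranges need fields ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Compute nSESA profiles from a structure
#'
#' Parses a PDB file, computes per-atom solvent-accessible surface area
#' with [shrake_rupley()] over the whole structure, sums it per residue,
#' and normalizes each CDR residue by its Gly-X-Gly reference area
#' ([reference_areas()]), clipping to `[0, 100]` percent.
#'
#' @param pdb_path PDB-format file.
#' @param ranges data.frame from [read_cdr_ranges()] (loop, chain, start,
#'   end).
#' @param probe,n_points Passed to [shrake_rupley()].
#' @return Named list `loop -> list(residues = character, nsesa = numeric)`
#'   with attribute `"provenance" = "computed"`.
#' @export
compute_nsesa <- function(pdb_path, ranges, probe = 1.4, n_points = 480) {
  pdb <- bio3d::read.pdb(pdb_path)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  at <- at[toupper(at$elesy) != "H", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", pdb_path, call. = FALSE)
  area <- shrake_rupley(cbind(at$x, at$y, at$z), at$elesy,
                        probe = probe, n_points = n_points)
  key <- paste(at$chain, at$resno)
  res_area <- tapply(area, key, sum)
  out <- list()
  for (i in seq_len(nrow(ranges))) {
    loop <- ranges$loop[i]
    chain <- ranges$chain[i]
    if (!chain %in% at$chain) {
      stop("chain '", chain, "' not present in ", pdb_path, call. = FALSE)
    }
    resnos <- seq.int(ranges$start[i], ranges$end[i])
    keys <- paste(chain, resnos)
    missing <- resnos[!keys %in% names(res_area)]
    if (length(missing) > 0) {
      stop("residues missing from structure (chain ", chain, "): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    res3 <- vapply(resnos, function(r) {
      unique(at$resid[at$chain == chain & at$resno == r])[1]
    }, "")
    res1 <- bio3d::aa321(res3)
    if (any(!res1 %in% names(.ref_areas))) {
      stop("unsupported residue type(s) in chain ", chain, ": ",
           paste(unique(res3[!res1 %in% names(.ref_areas)]), collapse = ", "),
           call. = FALSE)
    }
    ns <- 100 * as.numeric(res_area[keys]) / .ref_areas[res1]
    out[[loop]] <- list(residues = res1,
                        nsesa = pmin(100, pmax(0, ns)))
  }
  attr(out, "provenance") <- "computed"
  out
}

#' Exposure masks from an nSESA profile
#'
#' A residue is exposed when its nSESA strictly exceeds the loop threshold
#' (5% for CDR1/2, 20% for CDR3 by default). The masks are what
#' [extract_windows()] mode `"exposed"` applies.
#'
#' @param profile Named list `loop -> numeric` (percent), or the
#'   `loop -> list(residues, nsesa)` form from [compute_nsesa()].
#' @param thresholds Named per-loop thresholds (percent).
#' @return Named list `loop -> logical`.
#' @export
apply_thresholds <- function(profile, thresholds = default_thresholds()) {
  out <- list()
  for (loop in names(profile)) {
    v <- profile[[loop]]
    if (is.list(v)) v <- v$nsesa
    thr <- thresholds[[loop]]
    if (is.null(thr)) stop("no threshold for loop ", loop, call. = FALSE)
    out[[loop]] <- v > thr
  }
  out
}
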