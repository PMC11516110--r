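Package: tcrpcdist
Title: Physicochemical Distances, Clustering and Deorphanization for
    Alpha-Beta T-Cell Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes physicochemical distances between alpha-beta T-cell
    receptors (TCRs) from Atchley-factor-encoded 4-mer windows of the six
    CDR loops, optionally restricted to solvent-exposed residues (nSESA
    filtering). Provides UPGMA dendrograms with deterministic tie-breaking,
    clustering-quality metrics (colour changes and pMHC-distance) with
    permutation nulls, nearest-neighbour specificity prediction
    (top-k success, enrichment factors, distance-to-probability curves,
    cross-validated per-peptide AUC) and deorphanization calls, a
    Shrake-Rupley solvent-accessibility module for PDB structures, a
    synthetic labelled-repertoire generator for end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    bio3d,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
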