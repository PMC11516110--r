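# tcrpcdist

Physicochemical distances, clustering-quality metrics and
nearest-neighbour specificity prediction (deorphanization) for paired
αβ T-cell receptor (TCR) repertoires.

## The problem

A TCR recognizes a peptide presented by an MHC molecule (pMHC) mainly
through its six complementarity-determining region (CDR) loops. Receptors
with similar loop physicochemistry tend to bind the same epitope, so a
good distance between TCRs lets you (i) cluster a repertoire into likely
specificity groups and (ii) transfer a known specificity from a reference
TCR to an "orphan" TCR of unknown specificity sitting nearby — which is
how tumour-infiltrating lymphocytes get deorphanized for personalized
immunotherapy.

## The metric

Each CDR loop is decomposed into sliding 4-mer windows. Every window is
encoded as a 4×5 matrix of the five Atchley factors (hydrophobicity,
secondary-structure propensity, size/mass, codon degeneracy, electric
charge). The distance between two windows is the Manhattan distance of
their factor matrices,

d(M₁, M₂) = Σᵢ₌₁..₄ ( |H₁ᵢ−H₂ᵢ| + |SS₁ᵢ−SS₂ᵢ| + |SM₁ᵢ−SM₂ᵢ| + |CD₁ᵢ−CD₂ᵢ| + |ES₁ᵢ−ES₂ᵢ| ),

normalized by the largest value attainable over the residue alphabet so
it lies in [0, 1]. The distance between two corresponding loops is the
**minimum** over all n×m window pairs; the distance between two TCRs is
the weighted sum over loops (default 30% per CDR3, 10% per CDR1/CDR2);
within a repertoire all pairwise distances are finally divided by the
largest one. Three variants:

* `cdr3b` — CDR3β only (bulk data without chain pairing), with the
  junction framework (first 4 / last 3 residues) trimmed;
* `6cdrs` — all six loops, CDR3s trimmed, germline loops taken in full;
* `3d` — all six loops, windows restricted to solvent-exposed residues
  (per-residue nSESA > 5% for CDR1/2, > 20% for CDR3), so windows may
  span residues that are non-consecutive in sequence.

nSESA profiles can be supplied as TSV or computed from a PDB structure by
the built-in Shrake–Rupley solvent-probe surface module, normalized per
residue by published Gly-X-Gly reference areas.

On top of the matrix the package builds deterministic UPGMA dendrograms
and scores how well specificity labels group on them (circular
colour-change count; pMHC-distance = mean cophenetic distance of
same-peptide leaf pairs, peptides equally weighted), with seeded
permutation nulls; and it predicts specificities by nearest-neighbour
screening (top-k success, enrichment factors, distance→share-probability
curves, cross-validated per-peptide AUC, threshold-gated
deorphanization calls).

## Worked example

```r
library(tcrpcdist)

rep <- generate_repertoire(generator_config(), seed = 42)  # 8 groups x 5 TCRs + 10 singletons
dm  <- pairwise_matrix(rep, variant = "6cdrs")
dm
#> <tcr_distmat> 50 TCRs, variant 6cdrs, normalization constant 0.4154

tree   <- upgma(dm)
labels <- setNames(rep$peptide, rep$id)
colour_changes(tree, labels)                       # 18 = number of labels: perfect grouping
pmhc_distance(tree, labels)$overall                # 0.1
permutation_null(dm, labels, "pmhc_distance", B = 1000, seed = 42)
#> null mean 0.679, p = 0.000999

topk_success(rep, "6cdrs", k = 10, dm = dm)$success
#> 0.8   (the 10 singletons can never find a partner: 40/50 is the ceiling)

orphans <- as_repertoire(transform(as.data.frame(rep[1:2, ]),
                                   id = c("orphan1", "orphan2"), peptide = NA))
deorphanize(orphans, rep, variant = "6cdrs")[, c("orphan", "called", "peptide", "distance", "ef")]
#>    orphan called peptide distance ef
#> 1 orphan1   TRUE   PEP01        0  5
#> 2 orphan2   TRUE   PEP01        0  5
```

A colour-change count of 18 on 18 distinct labels means the dendrogram
groups every specificity into one contiguous arc; the permutation p-value
says label-blind distance permutation essentially never does as well. The
two orphans (copies of PEP01 members) are called at distance 0 with a
5-fold enrichment of PEP01 among their ten nearest references.

A shell front-end with `simulate` / `distance` / `cluster` / `predict` /
`nsesa` subcommands is installed at
`system.file("cli", "tcrpcdist.R", package = "tcrpcdist")`.

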