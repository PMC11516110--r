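---
title: "Physicochemical TCR distances: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physicochemical TCR distances: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrpcdist)
```

## The model

TCR–pMHC recognition is dominated by short, contiguous-in-space patches
of the six CDR loops rather than by whole-loop sequence identity. The
metric implemented here therefore compares loops through their 4-residue
windows: every admissible window is encoded as a 4×5 matrix of Atchley
factors (five published orthogonal summaries of amino-acid
physicochemistry: hydrophobicity/polarity, secondary-structure
propensity, size/mass, codon degeneracy, electric charge), window pairs
are scored by the Manhattan distance between their factor matrices, and
the **distance between two loops is the minimum over all window pairs** —
two loops count as close as soon as one pair of 4-mers matches
physicochemically, no alignment or gap model involved. A TCR pair's
distance is the weighted sum over loops, and a repertoire's pairwise
distances are finally divided by their maximum.

Because of the min-over-windows, the metric is a similarity-driven
dissimilarity, not a metric in the mathematical sense: it is symmetric,
non-negative and zero on identical loop sets, but the triangle
inequality can fail. The test-suite asserts exactly the properties that
hold and nothing stronger.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| CDR weights | 0.3 per CDR3, 0.1 per CDR1/2 | fractions summing to 1 | CDR3 junctions dominate peptide contacts; germline CDR1/2 refine chain pairing. `weight_scheme("cdr3b")` puts all weight on CDR3β for unpaired bulk data. |
| CDR3 trim | first 4 / last 3 residues | positions | conserved C…F junction framework is rarely peptide-facing; applied in the sequence-only variants, including the CDR3β-only one (flag `cdr3_trim` exposes the choice). |
| nSESA thresholds | 5% (CDR1/2), 20% (CDR3) | percent, strict `>` | buried residues cannot contact the epitope; CDR3 needs the stricter cut because its framework flanks are partially occluded. Boundary values are excluded under both phrasings by standardizing on strict comparison. |
| call threshold | 0.15 | normalized distance, strict `<` | below this distance the probability that two receptors share a pMHC is high enough to act on; calls carry the enrichment factor and, when a share-probability curve is supplied, the empirical probability band. |
| permutation count B | ≥ 100 | — | add-one-corrected p-values `(1 + #{null ≤ obs})/(B + 1)`; B = 100 is the floor at which p < 0.01 is attainable. |

## Numerical decisions

**Per-window normalization constant.** Window scores are divided by
`k × max_residue_distance()` — the window length times the largest
summed absolute factor difference over all residue pairs, a constant
derived from the Atchley table at load time. This puts every per-loop
score in [0, 1] *before* weighting, and the repertoire-level
max-normalization is applied afterwards. The constant itself is not
published; deriving it from the encoding table is the only
parameter-free choice consistent with scores that span [0, 1].

**Short loops and empty window sets.** If trimming or exposure
filtering leaves fewer than 4 residues, the loop falls back to its full
sequence (flagged on the `window_set`); if the loop itself is shorter
than 4 residues, windows of the shorter length are used and the two
loops are compared at the smaller width, with the normalization constant
scaled accordingly. This keeps the metric total and deterministic on
degenerate input instead of erroring on short germline loops.

**UPGMA determinism.** Average-linkage trees are rebuilt thousands of
times inside permutation nulls, so tie-breaking is pinned: the merged
pair is the one with the smallest distance, ties resolved by the
lexicographically smallest pair of minimal original leaf indices, and at
each merge the subtree containing the smaller original index goes left.
Cophenetic distances are invariant to these conventions (and are
cross-checked against `stats::hclust(method = "average")` in the tests);
the circular colour-change count is not, which is why the convention is
fixed and documented.

**Colour changes are circular.** Dendrograms of repertoires are drawn
as circles; label switches are counted between successive leaves
including the wrap-around, so a perfect grouping of k labels scores
exactly k.

**Permutation unit.** The null permutes the observed condensed distance
vector (reassigning distances to pairs), then re-clusters — not the
labels. This tests whether the *geometry* of the distances concentrates
same-specificity receptors, at fixed label multiplicities.

**Non-standard residues.** The Atchley table covers the 20 standard
amino acids and no substitution rule is defensible without data;
records containing `X`, `*` or lowercase letters are rejected with a
reason and surfaced in a rejection report, never silently dropped or
imputed.

## Solvent accessibility

The 3D variant needs per-residue normalized solvent-excluded surface
areas (nSESA). The packaged module is a Shrake–Rupley solvent-probe
computation (probe 1.4 Å, deterministic golden-spiral sampling, 480
points per atom by default) over PDB structures parsed with `bio3d`,
normalized by published theoretical Gly-X-Gly reference areas (Tien et
al. 2013) and clipped to [0, 100]%. Two caveats follow. First,
solvent-*accessible* areas from a probe method differ systematically
from solvent-*excluded* (molecular-surface) areas, so externally
produced SESA-based profiles and recomputed ones agree only within a
method tolerance — the module's correctness is therefore established
against closed-form sphere geometry (isolated atoms, two-sphere
overlaps, fully caged atoms) rather than against any particular surface
package. Second, reference areas are taken from the published
theoretical tripeptide values rather than rebuilt from in-package
tripeptide models: building correct extended-conformation side-chain
geometry is a large source of silent error, while the published values
are exact, inspectable constants.

Structure prediction is out of scope: users supply structures or nSESA
TSVs; one conformation per receptor is assumed.

## The bundled V-gene lookup is synthetic

CDR1/CDR2 are germline-encoded and usually reported only through V-gene
names. The package resolves them via a TSV lookup
(`vgene_cdr_lookup_synthetic.tsv`). The bundled table is a clearly
labelled **synthetic stand-in** — deterministic placeholder sequences,
not curated germline data — because a verified IMGT-derived table could
not be bundled; any curated replacement with the same three columns
(allele suffixes stripped) drops in via the `lookup` arguments, and its
CDR boundary convention should be documented by its provider. No test
and no reported quantity depends on the biological content of this
table: the zero-distance reproductions rest on orphan/reference pairs
that share V genes, so their germline loops are identical whatever the
lookup says.

## What the synthetic generator emulates — and what it does not

`generate_repertoire()` grows each specificity group from a seed
receptor by substituting a configurable number of interior CDR3
residues per chain (junction C…F termini conserved, replacement drawn
uniformly from the 19 alternatives), keeps the seed's V genes across
the group, and adds independent singletons with private labels. The
defaults — 8 specificities × 5 TCRs, 2 substitutions per chain, 10
singletons, CDR3 lengths 12–16 — are the conditions used throughout the
test-suite: they produce repertoires of 50 with tight but non-trivial
clusters and a 20% singleton floor on nearest-neighbour success, which
mirrors the role singletons played in the curated sets the method was
assessed on. Synthetic nSESA profiles bury each residue independently
(25% CDR1/2, 15% CDR3 — CDR3 loops protrude and are the most exposed),
drawing values strictly off the thresholds so exposure masks are
unambiguous.

The generator does **not** model VDJ recombination statistics, length
variation within a cluster, germline-biased substitution preferences,
cross-reactivity, or structurally correlated burial patterns. Passing
tests on this generator therefore establish internal correctness and
qualitative behaviour (cluster recovery beats permutation nulls;
nearest-neighbour AUC near 1 on tight clusters and 0.5 on shuffled
labels; share-probability enriched at distance 0), not quantitative
performance on real repertoires, which depends on modelled structures
and curated references that are not distributable here.

## Problem sizes in the shipped tests

The suite runs repertoires of 12–100 receptors, permutation nulls at
B = 100–1000, oracle equivalence on ≤ 10 receptors against exhaustive
nested-loop references, and 20-seed simulation properties at the
generator defaults — sizes chosen so every property is exercised at
full fidelity while the whole suite stays fast enough to run on every
change.

## Known limitations

* Dataset-dependent max-normalization means distances are comparable
  only within one computed matrix; cross-repertoire screening therefore
  normalizes the combined orphan + reference set, and distances from
  different runs must not be mixed.
* The triangle inequality is not guaranteed (min-over-windows).
* 4-mer features under-represent long CDR3 loops where more residues
  contact the antigen.
* The published clustering statistics of the 54-structure developmental
  set cannot be recomputed here because that set's per-receptor
  sequences are not redistributable with the package; the corresponding
  checks are present and fail with that diagnosis instead of being
  silently skipped.
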