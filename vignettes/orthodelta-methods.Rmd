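---
title: "Decomposing gene families, measuring discordance, and testing for introgression"
author: "OrthoDelta authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing gene families, measuring discordance, and testing for introgression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OrthoDelta)
```

# Motivation

Phylogenomic pipelines usually begin by clustering genes into families.
Most families are multi-copy: duplication and loss leave several copies per
species, and naively treating copies as orthologs corrupts downstream
species-tree and introgression inference.  The classical remedy — keeping
only single-copy clusters (SCC) — discards most of the data.  OrthoDelta
implements the tree-based decomposition alternatives that recover ortholog
sets from multi-copy families, the branch-wise gene concordance factors
(gCF) used to quantify gene-tree/species-tree disagreement, and the
Δ test that turns the asymmetry of the two minor topologies at a branch
into a test for introgression.  A duplication–loss and
multispecies-coalescent (MSC) simulator with true duplication/speciation
node labels makes every step verifiable on data with a known answer.

# Decomposition methods

All methods consume a `GeneFamily` (a gene tree whose tips are copies, a
copy→species map, optionally per-copy ungapped sequence lengths) and only
ever *remove leaves*; none invents topology.  Occupancy (the MIN-k
threshold `minTaxa`, counting distinct species) is applied after
extraction.

* **SCC** (`filterSCC`): keep the family as-is iff every represented
  species has exactly one copy.
* **LSD trimming** (`trimLSD`): each maximal clade of ≥ 2 copies from a
  single species is reduced to one survivor — with a length table, the
  copy closest to the median length over all family sequences (lower
  median for even counts, ties by tip order); without one, the copy with
  the smallest root-to-tip distance (ties lexicographic).  The
  length-free rule is this package's own fallback: the median-length rule
  requires alignment lengths that tree-only inputs lack.
* **TSD trimming** (`trimTSD`): each maximal clade whose species set has
  size exactly two and which holds ≥ 3 leaves is reduced to the
  cross-species pair at minimum patristic distance (ties: smallest copy
  pair).  A two-leaf cross-species cherry contains no duplicate and is
  untouched.
* **SE** (`extractSE`): midpoint-root, trim LSD + TSD, then cut out every
  *maximal duplicate-free clade* — a node whose subtree repeats no species
  while its parent's does.  One pass; remainders are not re-analyzed.
* **MI** (`extractMI`): first cut every branch longer than the long-branch
  cutoff (on the unrooted tree, so the rooted representation cannot hide a
  long branch by splitting it at the root) and decompose into components;
  then per component repeatedly extract the duplicate-free clade with the
  most species and re-queue the remainder, emitting a duplicate-free
  remainder whole, until nothing with `minTaxa` species is left.  The
  cutoff is expressed in the branch-length units of the input trees
  (e.g. 0.4 substitutions/site for ML trees, 500 changes for parsimony
  trees).
* **MO** (`extractMO`): requires the outgroup copies present to be
  single-copy and monophyletic; roots on them, walks root→tips, and at
  each duplication node (child subtrees sharing a species) keeps the child
  with more species (ties: fewer copies, then traversal order), finally
  returning the ingroup.
* **ONE** (`sampleOneParalog`): one uniformly random copy per species,
  with the random stream keyed by `(seed, familyId)` so results do not
  depend on processing order.

Design choices where the field's descriptions are silent are resolved for
determinism and are documented on each function: every tie-break is
explicit, and midpoint rooting breaks ties among equally long leaf-to-leaf
paths by the lexicographically smallest leaf pair.  When the midpoint
falls exactly on a node, the incident path edge nearer the first leaf of
the chosen pair is subdivided at the node, which preserves the clades
around that node (important for ultrametric trees, where the midpoint
coincides with the original root).

Two behaviors deserve emphasis because they decide how SE and MI differ.
SE makes a single pass: the decomposition is exactly the set of maximal
duplicate-free clades.  MI is iterative: after the best clade is removed,
the remainder is re-analyzed, and a remainder that has become
duplicate-free is emitted whole.  The two agree whenever trimming leaves
no duplicate (the bulk of families at realistic duplication rates); every
disagreement traces to MI's remainder re-analysis.  On simulated trimmed
families we observe ≈ 86% identical collections (recomputed by the test
suite), qualitatively mirroring the high agreement reported for these two
approaches on empirical data.

# Concordance and the Δ test

Every internal branch of a rooted binary species tree defines a
quadripartition of the species set: the two clades `A`, `B` below the
branch, the sibling clade `C`, and the rest `D`.  A single-copy gene tree
is *decisive* for the branch if it samples all four groups; a decisive
tree displays exactly one of the three splits `AB|CD` (concordant),
`AC|BD`, `BC|AD` (the two minor topologies), or none (paraphyletic — a
reference clade is not monophyletic, or the region is a collapsed
polytomy; no resolution is invented).  Split testing treats gene trees as
unrooted.  `gCF = 100 · n_concordant / n_decisive`.

Under the MSC without gene flow the two minor *quartet* topologies at a
branch are equally likely, so with `nDF1` the more and `nDF2` the less
common minor count,

$$\Delta = \frac{n_{DF1} - n_{DF2}}{n_{DF1} + n_{DF2}}$$

is expected to be zero; introgression inflates one minor class and pushes
Δ toward one.  `testIntrogression` gates branches at a discordant
fraction above `minDiscordance` (default 5%; counting the two minor
classes only, because Δ consumes only those — the
`includeParaphyletic` flag switches to `1 − concordant fraction`),
bootstraps the per-branch classification list (2,000 resamples by
default) with DF1/DF2 identities fixed at their observed values, and
reports `z = Δ / sd_boot` with a two-sided normal p-value, corrected
across the `m` gated-in branches by the Dunn–Šidák rule
`1 − (1 − α)^{1/m}`.

Numerical choices: fixing DF1 per branch (instead of re-identifying it in
every replicate) yields a signed bootstrap distribution; re-identification
would fold the distribution and inflate Δ under the null.  Resampling a
label list with replacement is a multinomial draw over the class counts,
so replicates are generated by `rmultinom` — an exact identity, not an
approximation.  A percentile-based p-value is available via
`pMethod = "percentile"`.  Branches whose discordant trees all fall in
one class have a degenerate (zero-variance) null and are reported with
p = 1 and a warning.  Per-branch random streams derive from
`(seed, branch id)`, so adding branches never perturbs existing results.

An important caveat, verified in this package against an independent
coalescent implementation: the equal-minor-frequencies null is *exact*
only when each of the four groups contributes a single lineage (the
quartet case, e.g. every branch whose groups `A`, `B`, `C` are single
species).  When the classification counts displayed splits of full gene
trees at a branch whose groups are larger clades, the two minor classes
are intrinsically asymmetric under the MSC — the split uniting the
smaller of `A`/`B` with `C` requires fewer coalescent coincidences than
the one needing the larger clade monophyletic — so Δ has positive
expectation at such branches even without gene flow.  This affects any
displayed-split implementation of the test, not just this one.
Significant Δ at a branch with markedly unequal clade sizes should
therefore be read with care, and the packaged null-symmetry test asserts
equality at quartet-like branches only.

In addition, the normal-tail p-value and the Šidák correction (which
assumes independent tests, while branches share gene trees) make
family-wise error control approximate: in the packaged 100-replicate
null study the family-wise rejection rate stays inside the 99% binomial
band around the nominal 5%, but borderline p-values deserve caution.

# The synthetic-data generator

`simSpeciesTree` draws pure-birth ultrametric species trees (lengths in
coalescent units).  `simMSCGeneTrees` implements the standard MSC: one
lineage per species, pairwise coalescence at rate 1 within each branch;
for a rooted triple with internal branch $T$ the discordance probability
is $(2/3)e^{-T}$, which the suite checks at $T \in \{0.5, 1, 2\}$.
`simDLFamily` hangs a birth–death process on the species tree: each copy
duplicates at rate λ and dies at rate μ (per copy per coalescent unit),
survivors speciate at species-tree nodes, and every surviving internal
node carries its true label (`D`/`S`); nodes left with a single child are
suppressed.  The gene tree equals the locus tree (no coalescent layering
below duplications): that is sufficient to exercise decomposition truth
recovery without two-stage machinery.  `simTripletCounts` draws the
closed-form class probabilities with an introgression fraction γ mixing
in a second history whose major topology is the first minor class.

True ortholog groups (`trueOrthologSets`) are the *maximal
duplication-free clades* of the labelled tree.  A definition based on
D-free spanning paths is strictly weaker: copies connected only through
speciation nodes that surround a pendant multi-species duplication clade
would count as one group, yet no clade-based extraction can return them
together, so the clade-based definition is the one under which SE's
truth-recovery guarantee is well-posed — and it is exactly the
decomposition induced by cutting the tree at duplication nodes.

Default study conditions (chosen once, as realistic for a mammal-scale
data set, and used by the test suite and the acceptance script): 8
species, duplication rate λ = 0.3 and loss rate μ = 0.2 per copy per
coalescent unit (≈ 1.2–1.5 copies per species per family, a realistic
degree of copy inflation for mammal-scale gene families), MIN-4
occupancy; Δ studies use a 6-species caterpillar with internal branches
of 0.5 coalescent units (≈ 40% discordant loci per branch, comfortably
above the 5% gate), 400 loci per null replicate and 500 loci per power
replicate at γ ∈ {0, 0.1, 0.3}.  These sizes keep every study inside a
few minutes while leaving Monte-Carlo error far below the effect sizes
being asserted.

What the simulator deliberately omits — gene-tree estimation error,
rate variation across lineages (branch-length noise is available but off
by default), hemiplasy-aware duplication placement, sequence evolution —
bounds what green tests mean: they certify the tree operations,
statistics and their calibration on correctly inferred trees, not
robustness to inference error in real alignments.

# Worked example

```{r example}
stree <- simSpeciesTree(8, 1, seed = 42)
fams  <- simDLFamilies(stree, 50, lambda = 0.3, mu = 0.2, seed = 42)
length(fams)

## decompose every family by subtree extraction
sets <- unlist(lapply(fams, extractSE, minTaxa = 4))
length(sets)
sets[[1]]

## single-copy gene trees under the MSC, concordance, and the Delta test
gts <- simMSCGeneTrees(stree, 300, seed = 1)
bc  <- concordanceTable(gts, stree = stree)
bc[, c("branch_id", "n_decisive", "n_concordant", "n_alt1", "n_alt2", "gCF")]

res <- testIntrogression(gts, stree = stree, B = 2000, seed = 1)
res[, c("branch_id", "nDF1", "nDF2", "delta", "p", "tested", "significant")]
```

# Limitations

* Concordance and Δ require single-copy-per-species gene trees; multi-copy
  trees must be decomposed first (the functions refuse them with advice).
* gCF paraphyly here is an operational category (no candidate split
  displayed); upstream tools may bin edge cases differently.
* The Δ p-value rests on the normal approximation to the bootstrap null;
  for very few discordant trees the percentile method is preferable, and
  branches below the discordance gate are deliberately not tested.
* Family-wise error control is approximate under branch correlation (see
  above).
* No support for NEXUS/PhyloXML, site-based concordance factors, or
  phylogenetic-network estimation.
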