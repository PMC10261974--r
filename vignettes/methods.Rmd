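---
title: "Comparative mitogenome evolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenome evolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`cnidmito` implements the statistical core of a comparative mitochondrial
genome study of the kind carried out for cnidarians: many annotated
mitogenomes are compared for nucleotide composition, per-gene diversity,
selection pressure on protein-coding genes, and the order of the 13
protein-coding genes plus the two rRNAs around the molecule. Anthozoan
mitogenomes are circular and medusozoan ones linear; tRNA content varies
too much across the phylum to carry comparative signal, which is why the
gene-order alphabet is fixed at those 15 genes.

Every stage can be exercised without real data: a seeded simulator
generates mitogenomes with a known phylogeny, known per-branch selection
parameters, and a known log of gene-order rearrangements, so each
algorithm is validated against ground truth or an independent oracle.

# Composition statistics

Strand asymmetry is summarised by AT-skew $= (A-T)/(A+T)$ and GC-skew
$= (G-C)/(G+C)$ over the unambiguous base counts of the plus strand as
deposited. Ambiguity codes are excluded from every denominator; an empty
denominator yields `NA`, never an error, so degenerate records flow
through group summaries harmlessly.

Codon usage is summarised as RSCU: for codon $c$ in a synonymous family
$F$, $\mathrm{RSCU}(c) = n_c \cdot |F| / \sum_{c' \in F} n_{c'}$, so a
uniformly used family sits at 1 for every member. The genetic code
defaults to NCBI translation table 5 (invertebrate mitochondrial), the
convention for this taxon set, and is configurable; stop codons are never
counted. Group summaries report mean ± sample SD ($n-1$ denominator),
with single-member groups flagged and given SD 0. Two-group location
comparisons use the two-sided Wilcoxon rank-sum test — exact enumeration
when both groups have at most eight observations without ties, the
tie-corrected normal approximation otherwise — because a rank test is the
only test family the report surfaces use. The AT/GC skew association is
Pearson's $R$, the conventional reading of an "R" with a p value.

# Nucleotide diversity

Per-gene alignments are consumed, not computed (the simulator is
indel-free, so its alignments are trivially exact). The column filter is a
deliberate, documented stand-in for automated block filtering: policy
`strict` removes every column containing a gap or ambiguity, policy
`none` passes through. Because the filter differs from any particular
external tool's heuristics, filtered lengths are method-sensitive and are
not treated as reproducible constants.

Diversity is Nei's $\pi$: the mean over unordered sequence pairs of
(differences / comparable sites), a site being comparable when both
members carry an unambiguous base. No multiple-hit correction is applied,
matching the standard per-site $\pi$ definition. A column is polymorphic
iff at least two distinct unambiguous bases occur in it.

# Selection analysis

Two routes to $\omega = dN/dS$ are implemented and kept strictly apart so
one can check the other.

**NG86 counting.** Synonymous site counts per codon come from
mutation-fate enumeration: each of the nine single-nucleotide changes is
classified, mutations to stop codons counting toward the nonsynonymous
fraction so that $N + S = 3 \times$ codons compared. Codon differences at
2–3 positions are averaged over all orderings of single-nucleotide paths,
excluding paths through stop codons (falling back to all paths in the
rare case every ordering is blocked). Proportions are corrected with
Jukes–Cantor, $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$; $p \ge 3/4$
yields an `NA` rate rather than a fabricated distance.

**GY94 branch models.** The codon rate matrix allows single-nucleotide
changes only, with multiplier $\kappa$ for transitions, $\omega$ (of the
branch's class) for nonsynonymous changes, and the target codon's
equilibrium frequency (F3x4 by default: position-specific nucleotide
frequencies multiplied and renormalised over sense codons; frequencies
are floored at $10^{-8}$ to keep the matrix irreducible). All class
matrices share one time scale — branch lengths are expected substitutions
per codon under the first class's $\omega$ — so class $\omega$s are
comparable. Likelihoods come from Felsenstein pruning with per-node
rescaling; transition matrices use the symmetric eigendecomposition
available for reversible chains.

Branch classes mirror the standard branch-model vocabulary: one-ratio
(single $\omega$), two-ratio (a foreground clade, including its stem
edge, against the background), free-ratio (one $\omega$ per branch, with
the two edges at a two-degree root merged because they are a single
branch of the unrooted tree). Fitting maximises over $\log\kappa \in
[\log 0.1, \log 20]$ and each $\log\omega \in [\log 10^{-4}, \log 10]$
with L-BFGS-B from a fixed grid of starts; for nested models the fitted
null is always included as a start, which guarantees
$\ell_\text{alt} \ge \ell_\text{null}$ up to optimizer tolerance and
makes the likelihood-ratio test ($2\Delta\ell$ against $\chi^2$ with the
difference in free $\omega$ count as df, clipped at zero) well defined.
Branch lengths are fixed from the input tree by default, decoupling
branch-length and $\omega$ estimation at desk scale; joint per-edge
optimisation is available for small trees via
`optimize_branch_lengths = TRUE`. Clade-level contrasts collect
free-ratio $\omega$s by the clade each branch belongs to (all descendant
tips inside the clade) and compare clade pairs with the rank-sum test,
star-coded at .05/.01/.001.

These fits are a fresh implementation, not a wrapper around an external
phylogenetics program; published $\omega$ values obtained with other
software should be expected to agree directionally, not digit-for-digit,
since such programs embed many internal defaults of their own.

# Gene orders

A genome's gene order is the signed sequence of the 15 alphabet genes by
start coordinate, orientation from the strand. Records missing any
alphabet gene are excluded (a pattern must be a permutation); duplicate
annotations keep the earliest start. Orders are compared in one circular
space: the canonical form rotates COX1 first and reflects the whole order
when COX1 is on the minus strand, so rotations and reflections of the
same circular arrangement collapse to one representative. Linear
(medusozoan-style) orders are embedded in the same space, with their
provenance retained — the comparison is what matters, not the topology of
the molecule. Genes annotated inside a host gene's intron (the
hexacorallian NAD5 arrangement) are ordered by their own start
coordinates, the host by its first exon, which yields a total order.

**Common intervals.** A common interval of two orders is a gene subset,
size 1 through $n$, contiguous in both (signs ignored). Counting includes
singletons and the full set, so identical orders share $n(n+1)/2 = 120$
intervals at $n = 15$. The package's counting convention is explicit and
self-consistent; published counts under other tools' unstated conventions
are not comparable number-for-number.

**Events.** Inversion reverses a block and flips its signs; transposition
moves a block; reverse transposition moves and inverts; TDRL duplicates
the order in tandem and keeps, per gene, the left or right copy. TDRL is
sign-preserving, and the minimum number of TDRLs sorting an unsigned
permutation is $\lceil \log_2 k \rceil$ where $k$ counts maximal runs of
consecutive values at increasing positions — verified in the tests
against a breadth-first search over all TDRL outcomes for every
permutation up to $n = 6$.

**Scenarios.** `infer_scenario()` is layered: exact equality, then direct
single-event detection (O(n) pattern checks against the relabelled
identity), then two-event composites by trying every candidate first
event — preferring composites of the elementary events (inversions,
transpositions) before admitting reverse transpositions, since a reverse
transposition is itself a compound move — and finally a sound fallback:
invert each maximal run of wrongly-oriented genes, then sort with the
minimum number of TDRLs. Every returned scenario is replayed internally
and must transform source into target exactly; the fallback layer sets a
`heuristic` flag because only the ≤2-event layers are minimal by
construction.

**Ancestral orders.** Each signed adjacency (including the circular
closing one) is a binary character scored with Fitch bottom-up/top-down
passes; at ambiguous roots the state with majority leaf support wins.
Each internal node's selected adjacencies are then assembled greedily
into a single circular tour — highest leaf support first, ties
lexicographic, premature cycles refused — and any remaining open ends are
joined deterministically, flagging the node as repaired. Per-character
optima need not be simultaneously realisable as a permutation, which is
why assembly, not Fitch alone, produces the order; on the low-event
regimes the method targets, the tests show the assembled assignment
reaches the restricted-Sankoff optimum. Multifurcations are resolved to
binary nodes with zero-length edges before scoring.

# Trees

All trees the package builds are distance trees and are labelled as such:
p, JC69 or K2P distances, Saitou–Nei neighbor joining, and classic
(column-resampling) bootstrap support. Maximum-likelihood and Bayesian
tree inference are out of scope by design; no claim the package prints
depends on an ML topology. Negative NJ branch lengths are clamped to zero
with the deficit moved to the sibling edge, preserving path lengths where
possible. Saturated pairwise distances take the largest defined distance
in the matrix, with a log entry.

# The simulator

`simulation_config()` defaults describe a small but realistic clade:

* 12 leaves on a Yule tree, rescaled to mean root-to-tip depth 0.3
  expected substitutions per codon — an interspecific, within-phylum
  divergence level;
* $\kappa = 2$, a single purifying $\omega = 0.1$, A+T fraction 0.62
  (the observed cnidarian average is near 62%), F3x4-style frequencies
  built from that single AT parameter;
* gene-order event rates per unit branch length of 1 (inversion), 0.5
  (transposition), 0.25 (reverse transposition), 0.25 (TDRL) — a handful
  of events across a small tree, matching the sparse rearrangement
  regime the method suite targets;
* 13 protein-coding genes at realistic codon lengths, two rRNAs laid in
  as unevolved clonal sequences (they carry order information only), and
  AT-matched spacers.

Codon sequences evolve by Gillespie simulation under exactly the rate
matrix the likelihood uses; the per-edge event log, per-branch classes,
substitution counts and seed are all retained, and replaying the log from
the root must reproduce every leaf order byte-for-byte (tested). A single
RNG stream is seeded once per run, so outputs are fully deterministic.

What the simulator does not emulate — and what passing tests therefore do
not establish about real data: indels and alignment error (sequences are
gap-free by design), annotation error and naming inconsistency beyond the
synonym table, tRNAs and introns, compositional heterogeneity across
lineages, linear-molecule end effects, and recombination. Conclusions
about those phenomena require real datasets.

# Validation design and problem sizes

Every algorithm with a nontrivial implementation is checked against an
independent route: common intervals against exhaustive subset
enumeration (orders up to $n = 8$); the TDRL formula against BFS (all
permutations to $n = 6$); NG86 against a fresh pathway-enumeration
implementation (random 50-codon pairs); the pruning likelihood against
exhaustive summation over internal-node states (4 taxa, 30 codons, where
the $62^3$ internal-state grid is still tractable); ancestral reconstruction
against restricted Sankoff over observed patterns (trees to 6 leaves, up
to 2 planted events). Statistical calibration uses 6-taxon alignments:
300 codons and 50 replicates for foreground/background ordering recovery
($\omega$ 0.1 vs 0.5), and 150 codons and 200 replicates for the LRT
type-I error, sizes chosen to give stable rates while keeping the full
validation suite runnable on a laptop in minutes. The acceptance script
(`scripts/acceptance.R`) recomputes all of these from scratch under a
caller-supplied seed.

# Known limitations

Scenario minimality is guaranteed only up to two events; longer scenarios
are sound upper bounds and flagged. The greedy tour assembly can repair
conflicting adjacency sets arbitrarily (deterministically, but without
optimality claims) in high-rearrangement regimes. The branch-model
optimizer is a bounded quasi-Newton search from a small start grid;
pathological likelihood surfaces could in principle hold a better optimum
than any start reaches, which the multi-start plus nested seeding makes
unlikely but not impossible. Dataset-scale findings of the motivating
literature (genome-size extrema, pattern censuses over hundreds of
genomes) require the corresponding public accessions and are outside the
desk-scale validation perimeter.
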