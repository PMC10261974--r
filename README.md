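# cnidmito

Comparative analysis of animal mitochondrial genomes, built around the
cnidarian mitogenome: 13 protein-coding genes (PCGs) plus the two rRNAs,
circular in anthozoans and linear in medusozoans. The package is aimed at
molecular evolution researchers who want the full statistical chain of a
mitogenome comparison — composition, diversity, selection, gene order —
as tested, scriptable R functions rather than a collection of external
tools.

## What it computes

* **Composition** — base counts, A+T%, strand skews
  (AT-skew = (A−T)/(A+T), GC-skew = (G−C)/(G+C)), relative synonymous
  codon usage (RSCU) under the invertebrate mitochondrial code, group
  summaries (mean ± SD), Wilcoxon rank-sum group contrasts, and the
  Pearson correlation between AT and GC skew across genomes.
* **Diversity** — per-gene alignment filtering, segregating sites S, and
  Nei's nucleotide diversity π (mean pairwise difference per comparable
  site).
* **Selection** — ω = dN/dS two ways: NG86 pairwise counting
  (mutation-fate site counts, pathway-averaged differences, Jukes–Cantor
  correction) and a GY94-style codon likelihood with one-ratio,
  two-ratio (foreground clade vs background) and free-ratio branch
  models, maximised numerically, with likelihood-ratio tests and
  clade-level ω comparisons.
* **Gene order** — signed 15-gene circular orders in canonical form,
  exact pattern grouping, common-interval similarity, rearrangement
  scenarios over inversion / transposition / reverse transposition /
  TDRL (tandem duplication–random loss), TDRL distance
  (⌈log₂ k⌉ over consecutive-value runs), and ancestral gene orders by
  adjacency parsimony on a fixed tree.
* **Trees** — p/JC69/K2P distances, neighbor joining with non-negative
  branch lengths, classic bootstrap support, monophyly tests.
* **Simulation** — a seeded mitogenome-evolution simulator (Yule tree,
  Gillespie codon evolution under the same GY94 matrix the fits use,
  Poisson rearrangement events with a full ground-truth log) so every
  stage is verifiable without downloading data.

## Worked example

The `analysis/` directory holds the six numbered stages of the study as
thin drivers over the package; `Rscript analysis/01_simulate.R` through
`06_trees.R` regenerate everything under `results/`. Stage 1 simulates a
12-leaf clade (seed 42) with two planted rearrangement events; stage 5
then recovers the gene-order history:

```
3 gene-order pattern(s) among 12 genomes:
  GO1 (n = 6): +COX1 +rrnL +ATP6 +rrnS +NAD5 +CYTB
  GO2 (n = 4): +COX1 +rrnL +ATP6 +rrnS -CYTB -NAD5
  GO3 (n = 2): +COX1 -CYTB -NAD5 -rrnS -ATP6 -rrnL
Ancestral reconstruction: 2 event(s) inferred on the tree (2 planted).
Estimated root order: +COX1 +rrnL +ATP6 +rrnS +NAD5 +CYTB
True root order     : +COX1 +rrnL +ATP6 +rrnS +NAD5 +CYTB
```

GO2 and GO3 descend from GO1 by the two planted inversions; the
reconstruction assigns both events to the correct edges and recovers the
root arrangement exactly. Stage 4 fits branch models to the same data
(simulated under a single ω = 0.1):

```
ATP6  one-ratio omega=0.08337 | two-ratio foreground=0.09289;background=0.05151 | LRT p = 0.285
COX1  one-ratio omega=0.13163 | two-ratio foreground=0.14515;background=0.08510 | LRT p = 0.140
CYTB  one-ratio omega=0.10556 | two-ratio foreground=0.10532;background=0.10633 | LRT p = 0.981
NAD5  one-ratio omega=0.09286 | two-ratio foreground=0.09074;background=0.10059 | LRT p = 0.796
0 of 4 genes reject the one-ratio model at alpha = .05 (expected ~0 under the null).
```

One-ratio estimates straddle the true 0.1 and, the data being simulated
under the null, no gene rejects it.

A minimal interactive session:

```r
library(cnidmito)
cfg <- simulation_config(seed = 1)
sim <- simulate_mitogenomes(cfg)
composition_table(sim$records)[1:3, c("record_id", "length", "at_percent", "at_skew")]
orders <- lapply(sim$records, extract_gene_order)
group_patterns(orders)[[1]]$count
```

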