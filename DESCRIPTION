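Package: cnidmito
Title: Comparative Mitochondrial Genome Evolution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of animal mitochondrial genomes,
    built around the cnidarian mitogenome (13 protein-coding genes plus two
    rRNAs). Covers per-genome composition statistics (A+T content, AT/GC
    strand skew, relative synonymous codon usage), per-gene nucleotide
    diversity, codon-model selection analysis (NG86 pairwise dN/dS and a
    GY94-style branch model with one-ratio, two-ratio and free-ratio fits and
    likelihood-ratio tests), signed gene-order analysis (pattern grouping,
    common intervals, inversion/transposition/TDRL rearrangement scenarios,
    adjacency-parsimony ancestral gene orders), distance-based tree building,
    and a seeded mitogenome-evolution simulator that provides ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
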