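# Distance-based tree building and tree utilities: pairwise sequence
# distances (p, JC69, K2P), neighbor joining (with non-negative branch
# lengths), classic bootstrap support, and a monophyly predicate. These are
# explicit stand-ins for full ML/Bayesian inference; every tree the package
# reports is a distance tree.

#' Pairwise sequence distances from an alignment
#'
#' Models: `"p"` (proportion of differing comparable sites), `"jc"` (JC69,
#' d = -(3/4) ln(1 - 4p/3)), `"k2p"` (Kimura 2-parameter from transition /
#' transversion proportions). Sites with a gap or ambiguity in either member
#' of a pair are excluded pairwise. Saturated pairs (correction undefined)
#' get the largest defined distance in the matrix, with a log entry.
#'
#' @param aln An [alignment()].
#' @param model "p", "jc" or "k2p".
#' @return Symmetric distance matrix with sequence ids as dimnames.
#' @export
sequence_distance <- function(aln, model = c("p", "jc", "k2p")) {
  model <- match.arg(model)
  mat <- aln$matrix
  n <- nrow(mat)
  if (n < 2) stopf("need >= 2 sequences")
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  saturated <- FALSE
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- mat[i, ] %in% NUCS & mat[j, ] %in% NUCS
    if (!any(ok)) stopf("pair (%s, %s) has no comparable sites", aln$ids[i], aln$ids[j])
    a <- mat[i, ok]; b <- mat[j, ok]
    p <- mean(a != b)
    val <- switch(model,
      p = p,
      jc = if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_,
      k2p = {
        ts <- mean((a %in% c("A", "G") & b %in% c("A", "G") |
                    a %in% c("C", "T") & b %in% c("C", "T")) & a != b)
        tv <- p - ts
        w1 <- 1 - 2 * ts - tv; w2 <- 1 - 2 * tv
        if (w1 > 0 && w2 > 0) -0.5 * log(w1) - 0.25 * log(w2) else NA_real_
      })
    d[i, j] <- val; d[j, i] <- val
  }
  if (anyNA(d)) {
    saturated <- TRUE
    mx <- max(d, na.rm = TRUE)
    cm_log$add(sprintf("%d saturated pairs set to max observed distance %.4f",
                       sum(is.na(d)) / 2, mx))
    d[is.na(d)] <- mx
  }
  d
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Canonical Saitou-Nei neighbor joining (via ape), then any negative
#' branch length is clamped to zero with the deficit moved onto its sibling
#' branch so path lengths are preserved where possible.
#'
#' @param matrix Symmetric distance matrix (zero diagonal, dimnames set).
#' @param tolerance Largest tolerated asymmetry.
#' @return An `ape::phylo` (unrooted).
#' @export
nj_tree <- function(matrix, tolerance = 1e-8) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stopf("distance matrix must be square")
  if (nrow(matrix) < 3) stopf("need >= 3 labels")
  if (max(abs(matrix - t(matrix))) > tolerance)
    stopf("distance matrix asymmetric beyond tolerance")
  if (any(diag(matrix) != 0)) stopf("distance matrix diagonal must be zero")
  tr <- ape::nj(as.dist(matrix))
  # clamp negative branch lengths, pushing the deficit to the sibling edge
  repeat {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[which.min(tr$edge.length[neg])]
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sibs)) {
      s <- sibs[1]
      tr$edge.length[s] <- tr$edge.length[s] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr
}

#' Bootstrap support by column resampling
#'
#' Classic Felsenstein bootstrap: resample alignment columns with
#' replacement B times (seeded), rebuild the tree with `builder`, and score
#' each internal bipartition of the full-data tree by the percentage of
#' replicates containing it.
#'
#' @param aln An [alignment()].
#' @param builder Function alignment -> `phylo` (default: JC distances +
#'   [nj_tree()]).
#' @param B Number of replicates.
#' @param seed Integer seed.
#' @return The full-data tree with `node.label` holding support percentages
#'   (root label empty).
#' @export
bootstrap_support <- function(aln, builder = NULL, B = 100, seed = 1) {
  stopifnot(B >= 1)
  builder <- builder %||% function(a) nj_tree(sequence_distance(a, "jc"))
  full <- builder(aln)
  set.seed(seed)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(aln$length, aln$length, replace = TRUE)
    reps[[b]] <- builder(alignment(aln$matrix[, cols, drop = FALSE], gene = aln$gene))
  }
  part <- ape::prop.part(reps)
  counts <- ape::prop.clades(full, part = part, rooted = FALSE)
  counts[is.na(counts)] <- 0
  full$node.label <- as.character(round(100 * counts / B))
  full
}

#' Is a label set monophyletic?
#'
#' TRUE iff `label_set` forms a clade of the tree rooted at
#' `outgroup_label`.
#'
#' @param tree An `ape::phylo`.
#' @param label_set Tip labels to test.
#' @param outgroup_label Tip used to root the tree.
#' @return Logical.
#' @export
is_monophyletic <- function(tree, label_set, outgroup_label) {
  missing <- setdiff(c(label_set, outgroup_label), tree$tip.label)
  if (length(missing)) stopf("labels absent from tree: %s",
                             paste(missing, collapse = ", "))
  rooted <- ape::root(tree, outgroup = outgroup_label, resolve.root = TRUE)
  ape::is.monophyletic(rooted, label_set)
}
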