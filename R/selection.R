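# dN/dS machinery: NG86 pairwise counting (mutation-fate enumeration with
# pathway averaging and Jukes-Cantor correction) and a GY94-style codon
# likelihood with branch classes (one-ratio / two-ratio / free-ratio),
# maximised numerically, plus likelihood-ratio tests and clade-level omega
# comparisons.

## ---- code structure cache -------------------------------------------------

.code_cache <- new.env(parent = emptyenv())

# For a genetic code: sense codons, their amino acids, and for each codon its
# single-nucleotide neighbours with transition/synonymous flags. Neighbours
# that are stop codons get target index NA.
code_structure <- function(genetic_code_id = "5") {
  id <- as.character(genetic_code_id)
  if (!is.null(.code_cache[[id]])) return(.code_cache[[id]])
  gc <- genetic_code(id)
  sc <- sense_codons(id)
  aa <- gc[sc]
  ncod <- length(sc)
  tgt <- matrix(NA_integer_, ncod, 9)
  ts <- matrix(FALSE, ncod, 9)
  syn <- matrix(FALSE, ncod, 9)
  for (i in seq_len(ncod)) {
    nb <- codon_neighbours(sc[i])
    for (k in seq_along(nb)) {
      j <- match(nb[k], sc)
      tgt[i, k] <- j
      p <- which(strsplit(sc[i], "")[[1]] != strsplit(nb[k], "")[[1]])
      ts[i, k] <- is_transition(substr(sc[i], p, p), substr(nb[k], p, p))
      if (!is.na(j)) syn[i, k] <- aa[i] == aa[j]
    }
  }
  out <- list(id = id, codons = sc, aa = unname(aa), tgt = tgt, ts = ts, syn = syn)
  .code_cache[[id]] <- out
  out
}

## ---- NG86 pairwise --------------------------------------------------------

# Synonymous site fraction per codon: of the 9 single-nucleotide changes,
# the synonymous non-stop fraction, scaled so each codon has 3 sites
# (changes to stop codons count as nonsynonymous fates).
ng86_sites <- function(codon_idx, cs) {
  syn <- cs$syn[codon_idx, , drop = FALSE]
  rowSums(syn) / 3
}

# Enumerate orderings of the differing positions between two codons, count
# synonymous/nonsynonymous steps averaged over paths avoiding stop codons
# (all paths if every ordering hits a stop).
ng86_path_counts <- function(c1, c2, gc) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0) return(c(sd = 0, nd = 0))
  perms <- if (d == 1) list(pos) else {
    pm <- permutations_of(d)
    lapply(seq_len(nrow(pm)), function(r) pos[pm[r, ]])
  }
  valid <- list(); all_counts <- list()
  for (ord in perms) {
    cur <- c1; sdc <- 0; ndc <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (gc[nxt] == "*") ok <- FALSE
      if (gc[cur] != "*" && gc[nxt] != "*" && gc[cur] == gc[nxt]) sdc <- sdc + 1
      else ndc <- ndc + 1
      cur <- nxt
    }
    all_counts <- c(all_counts, list(c(sd = sdc, nd = ndc)))
    if (ok) valid <- c(valid, list(c(sd = sdc, nd = ndc)))
  }
  use <- if (length(valid)) valid else all_counts
  colMeans(do.call(rbind, use))
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(n - 1)
  out <- NULL
  for (i in 1:n) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

#' NG86 pairwise dN/dS
#'
#' Nei-Gojobori (1986) counting: synonymous/nonsynonymous site counts by
#' mutation-fate enumeration (averaged over the two sequences), difference
#' counts averaged over all orderings of single-nucleotide paths between
#' differing codons (paths through stop codons excluded), and Jukes-Cantor
#' correction d = -(3/4) ln(1 - 4p/3). Proportions >= 3/4 give an NA rate.
#' Codon pairs where either member contains ambiguity or is a stop codon are
#' skipped with a log entry.
#'
#' @param seq1,seq2 Equal-length, gap-free, in-frame nucleotide strings.
#' @inheritParams genetic_code
#' @return List with `N`, `S` (site counts, N + S = 3 x compared codons),
#'   `Nd`, `Sd`, `pN`, `pS`, `dN`, `dS`, `omega` (NA when dS is 0 or
#'   undefined), `codons_compared`.
#' @export
ng86_pairwise <- function(seq1, seq2, genetic_code_id = "5") {
  if (nchar(seq1) != nchar(seq2)) stopf("sequence length mismatch")
  if (nchar(seq1) %% 3 != 0) stopf("length %d not divisible by 3", nchar(seq1))
  cs <- code_structure(genetic_code_id)
  gc <- genetic_code(genetic_code_id)
  cod1 <- split_codons(seq1); cod2 <- split_codons(seq2)
  usable <- codon_is_unambiguous(cod1) & codon_is_unambiguous(cod2) &
    cod1 %in% cs$codons & cod2 %in% cs$codons
  if (any(!usable))
    cm_log$add(sprintf("%d codon pairs with ambiguity or stops skipped", sum(!usable)))
  cod1 <- cod1[usable]; cod2 <- cod2[usable]
  nc <- length(cod1)
  if (nc == 0) stopf("no comparable codons")
  i1 <- match(cod1, cs$codons); i2 <- match(cod2, cs$codons)
  S <- (sum(ng86_sites(i1, cs)) + sum(ng86_sites(i2, cs))) / 2
  N <- 3 * nc - S
  diffs <- which(cod1 != cod2)
  Sd <- 0; Nd <- 0
  for (k in diffs) {
    pc <- ng86_path_counts(cod1[k], cod2[k], gc)
    Sd <- Sd + pc[["sd"]]; Nd <- Nd + pc[["nd"]]
  }
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jc(pS); dN <- jc(pN)
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  list(N = N, S = S, Nd = unname(Nd), Sd = unname(Sd),
       pN = pN, pS = pS, dN = dN, dS = dS, omega = omega,
       codons_compared = nc)
}

## ---- codon alignments -----------------------------------------------------

#' Construct a codon alignment
#'
#' Aligned in-frame coding sequences; sequences with internal stop codons
#' are dropped with a log entry.
#'
#' @param seqs Named character vector of equal-length in-frame sequences
#'   (length divisible by 3).
#' @param gene Gene label.
#' @inheritParams genetic_code
#' @return A `codon_alignment` list: `gene`, `ids`, `codons` (character
#'   matrix, rows = sequences), `genetic_code_id`.
#' @export
codon_alignment <- function(seqs, gene = "", genetic_code_id = "5") {
  stopifnot(is.character(seqs), length(seqs) >= 2)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stopf("unequal sequence lengths")
  if (lens[1] %% 3 != 0) stopf("alignment length %d not divisible by 3", lens[1])
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  gc <- genetic_code(genetic_code_id)
  keep <- rep(TRUE, length(seqs))
  codmat <- do.call(rbind, lapply(seqs, split_codons))
  for (i in seq_along(seqs)) {
    cods <- codmat[i, ]
    aa <- gc[cods[codon_is_unambiguous(cods)]]
    if (any(aa == "*")) {
      cm_log$add(sprintf("sequence %s has internal stop codons; dropped", ids[i]))
      keep[i] <- FALSE
    }
  }
  if (sum(keep) < 2) stopf("fewer than 2 sequences without internal stops")
  structure(list(gene = gene, ids = ids[keep],
                 codons = codmat[keep, , drop = FALSE],
                 genetic_code_id = as.character(genetic_code_id)),
            class = "codon_alignment")
}

## ---- GY94 likelihood ------------------------------------------------------

# Unscaled GY94 rate matrix over sense codons: q_ij = pi_j * kappa^[ts] *
# omega^[nonsyn] for single-nucleotide changes, 0 otherwise.
gy94_matrix <- function(kappa, omega, freqs, cs) {
  ncod <- length(cs$codons)
  Q <- matrix(0, ncod, ncod)
  for (k in 1:9) {
    j <- cs$tgt[, k]
    ok <- !is.na(j)
    rate <- freqs[j[ok]] *
      ifelse(cs$ts[ok, k], kappa, 1) *
      ifelse(cs$syn[ok, k], 1, omega)
    Q[cbind(which(ok), j[ok])] <- Q[cbind(which(ok), j[ok])] + rate
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Symmetric eigendecomposition of a reversible Q (q_ij pi_i = q_ji pi_j).
gy94_eigen <- function(Q, freqs) {
  rs <- sqrt(freqs)
  B <- (rs * Q) %*% diag(1 / rs)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       right = (1 / rs) * e$vectors,      # D^{-1/2} U
       left = t(e$vectors * rs))          # U' D^{1/2}
}

gy94_pmat <- function(eig, t) {
  eig$right %*% (exp(eig$values * t) * eig$left)
}

prepare_freqs <- function(codon_frequencies, aln) {
  cs <- code_structure(aln$genetic_code_id)
  if (is.character(codon_frequencies)) {
    codon_frequencies <- match.arg(codon_frequencies, c("f3x4", "uniform"))
    f <- if (codon_frequencies == "f3x4") {
      f3x4_frequencies(apply(aln$codons, 1, paste, collapse = ""), aln$genetic_code_id)
    } else uniform_codon_frequencies(aln$genetic_code_id)
  } else {
    f <- codon_frequencies
  }
  f <- f[cs$codons]
  f <- pmax(f, 1e-8)
  f / sum(f)
}

# Compress alignment columns into unique site patterns.
site_patterns <- function(aln) {
  cs <- code_structure(aln$genetic_code_id)
  idx <- matrix(match(aln$codons, cs$codons), nrow = nrow(aln$codons))
  key <- apply(idx, 2, paste, collapse = ",")
  uk <- unique(key)
  list(states = idx[, match(uk, key), drop = FALSE],
       weights = as.numeric(table(key)[uk]))
}

#' Label tree edges with branch classes
#'
#' Builds the per-edge class labels a branch model needs. `one_ratio` gives
#' every edge the same class; `two_ratio` labels edges whose descendant tips
#' all belong to `foreground_set` (including the stem edge of that clade) as
#' "foreground" and the rest "background"; `free_ratio` gives each edge its
#' own class, merging the two edges at a 2-degree root (they are one branch
#' of the unrooted tree).
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param model "one_ratio", "two_ratio" or "free_ratio".
#' @param foreground_set Tip labels spanning the foreground clade
#'   (two-ratio only; must be non-empty).
#' @return A `branch_class_tree` list: `tree`, `class` (per edge, in
#'   `tree$edge` row order).
#' @export
branch_class_tree <- function(tree, model = c("one_ratio", "two_ratio", "free_ratio"),
                              foreground_set = NULL) {
  model <- match.arg(model)
  ne <- nrow(tree$edge)
  if (model == "one_ratio") {
    cls <- rep("omega", ne)
  } else if (model == "two_ratio") {
    if (is.null(foreground_set) || !length(foreground_set))
      stopf("two_ratio model needs a non-empty foreground_set")
    missing <- setdiff(foreground_set, tree$tip.label)
    if (length(missing)) stopf("foreground tips absent from tree: %s",
                               paste(missing, collapse = ", "))
    desc <- edge_descendant_tips(tree)
    fg <- vapply(desc, function(tips) all(tips %in% foreground_set), TRUE)
    if (!any(fg)) stopf("no edges subtend only foreground tips")
    cls <- ifelse(fg, "foreground", "background")
  } else {
    cls <- paste0("b", seq_len(ne))
    root <- ape::Ntip(tree) + 1L
    root_edges <- which(tree$edge[, 1] == root)
    if (length(root_edges) == 2) cls[root_edges] <- cls[root_edges[1]]
  }
  structure(list(tree = tree, class = cls), class = "branch_class_tree")
}

# Tip labels descending from each edge (child side).
edge_descendant_tips <- function(tree) {
  ntip <- ape::Ntip(tree)
  lapply(seq_len(nrow(tree$edge)), function(i) {
    child <- tree$edge[i, 2]
    if (child <= ntip) tree$tip.label[child]
    else ape::extract.clade(tree, child)$tip.label
  })
}

#' GY94 branch-model log-likelihood
#'
#' Felsenstein pruning over the tree with a GY94-style rate matrix per
#' branch class: single-nucleotide codon changes only, factor `kappa` for
#' transitions, the branch class's omega for nonsynonymous changes, and the
#' target codon's equilibrium frequency. All class matrices share one time
#' scale: expected substitutions per codon equal the branch length under the
#' first class's omega.
#'
#' @param aln A [codon_alignment()].
#' @param bct A [branch_class_tree()] whose tree has branch lengths and
#'   whose tips match the alignment ids.
#' @param kappa Transition/transversion rate ratio (>= 0).
#' @param omega_by_class Named numeric vector, one omega per class label in
#'   `bct$class`; the first element sets the rate scale.
#' @param codon_frequencies "f3x4" (default), "uniform", or a named numeric
#'   vector over sense codons.
#' @return Log-likelihood (numeric scalar).
#' @export
gy94_loglik <- function(aln, bct, kappa, omega_by_class,
                        codon_frequencies = "f3x4") {
  freqs <- prepare_freqs(codon_frequencies, aln)
  sp <- site_patterns(aln)
  gy94_loglik_prepared(sp, aln, bct, kappa, omega_by_class, freqs)
}

# Inner likelihood on precompressed patterns; used by the optimizer.
gy94_loglik_prepared <- function(sp, aln, bct, kappa, omega_by_class, freqs,
                                 blens = NULL) {
  cs <- code_structure(aln$genetic_code_id)
  tree <- bct$tree
  classes <- bct$class
  if (!all(classes %in% names(omega_by_class)))
    stopf("omega_by_class missing classes: %s",
          paste(setdiff(unique(classes), names(omega_by_class)), collapse = ", "))
  blens <- blens %||% tree$edge.length
  if (is.null(blens)) stopf("tree has no branch lengths")
  ncod <- length(cs$codons)
  npat <- length(sp$weights)
  ntip <- ape::Ntip(tree)
  tipidx <- match(tree$tip.label, aln$ids)
  if (anyNA(tipidx)) stopf("tree tips absent from alignment: %s",
                           paste(tree$tip.label[is.na(tipidx)], collapse = ", "))

  # one eigendecomposition per distinct omega class
  mu <- NULL
  eigs <- list()
  for (cl in unique(classes)) {
    Q <- gy94_matrix(kappa, omega_by_class[[cl]], freqs, cs)
    if (is.null(mu)) {
      Qref <- gy94_matrix(kappa, omega_by_class[[1]], freqs, cs)
      mu <- -sum(freqs * diag(Qref))
      if (!is.finite(mu) || mu <= 0) stopf("degenerate rate scale")
    }
    eigs[[cl]] <- gy94_eigen(Q / mu, freqs)
  }

  tree_po <- ape::reorder.phylo(tree, "postorder")
  # carry the same ordering for classes and lengths
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  po_key <- paste(tree_po$edge[, 1], tree_po$edge[, 2])
  perm <- match(po_key, edge_key)
  classes_po <- classes[perm]
  blens_po <- blens[perm]

  partial <- vector("list", ntip + tree$Nnode)
  logscale <- numeric(ntip + tree$Nnode)
  for (i in seq_len(ntip)) {
    L <- matrix(0, ncod, npat)
    st <- sp$states[tipidx[i], ]
    known <- !is.na(st)
    L[cbind(st[known], which(known))] <- 1
    if (any(!known)) L[, which(!known)] <- 1
    partial[[i]] <- L
  }
  for (e in seq_len(nrow(tree_po$edge))) {
    parent <- tree_po$edge[e, 1]; child <- tree_po$edge[e, 2]
    P <- gy94_pmat(eigs[[classes_po[e]]], blens_po[e])
    contrib <- P %*% partial[[child]]
    contrib[contrib < 0] <- 0
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- contrib
      logscale[parent] <- logscale[child]
    } else {
      partial[[parent]] <- partial[[parent]] * contrib
      logscale[parent] <- logscale[parent] + logscale[child]
    }
    mx <- max(partial[[parent]])
    if (mx > 0 && (mx < 1e-200 || mx > 1e200)) {
      partial[[parent]] <- partial[[parent]] / mx
      logscale[parent] <- logscale[parent] + log(mx)
    }
  }
  root <- ntip + 1L
  site_l <- as.numeric(freqs %*% partial[[root]])
  if (any(site_l <= 0) || any(!is.finite(site_l))) {
    bad <- which(site_l <= 0 | !is.finite(site_l))[1]
    stopf("non-finite likelihood at site pattern %d", bad)
  }
  sum(sp$weights * (log(site_l) + logscale[root]))
}

## ---- model fitting --------------------------------------------------------

#' Fit a GY94 branch model by bounded maximum likelihood
#'
#' Maximises the [gy94_loglik()] over kappa in \[0.1, 20\] and each class
#' omega in \[1e-4, 10\] (log scale, L-BFGS-B) from a small deterministic
#' grid of starting points; for nested models (two-ratio, free-ratio) the
#' one-ratio optimum is included as a start, so the fitted log-likelihood
#' never falls below the nested null. Branch lengths are fixed from the
#' input tree by default.
#'
#' @param aln A [codon_alignment()].
#' @param tree `ape::phylo` with branch lengths; tips must match alignment ids.
#' @param model "one_ratio", "two_ratio" or "free_ratio".
#' @param foreground_set Tip labels of the foreground clade (two-ratio).
#' @param codon_frequencies See [gy94_loglik()].
#' @param optimize_branch_lengths Also optimise every branch length
#'   (log-bounded in \[1e-6, 10\]); intended for small trees.
#' @param null_fit Optional `codon_model_fit` of a nested model on the same
#'   data, used as an extra starting point (avoids refitting the null
#'   internally when the caller already has it).
#' @return A `codon_model_fit` list: `model`, `kappa`, `omega` (named per
#'   class), `lnL`, `convergence` (logical), `n_eval`, `classes`, `bct`.
#' @export
fit_branch_model <- function(aln, tree, model = c("one_ratio", "two_ratio", "free_ratio"),
                             foreground_set = NULL, codon_frequencies = "f3x4",
                             optimize_branch_lengths = FALSE, null_fit = NULL) {
  model <- match.arg(model)
  bct <- branch_class_tree(tree, model, foreground_set)
  freqs <- prepare_freqs(codon_frequencies, aln)
  sp <- site_patterns(aln)
  cls <- unique(bct$class)
  nb <- if (optimize_branch_lengths) nrow(tree$edge) else 0

  obj_count <- 0
  make_obj <- function() {
    function(par) {
      obj_count <<- obj_count + 1
      kappa <- exp(par[1])
      om <- setNames(exp(par[1 + seq_along(cls)]), cls)
      bl <- if (nb) exp(par[1 + length(cls) + seq_len(nb)]) else NULL
      ll <- tryCatch(
        gy94_loglik_prepared(sp, aln, bct, kappa, om, freqs, blens = bl),
        error = function(e) -Inf)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
  }
  lower <- c(log(0.1), rep(log(1e-4), length(cls)), rep(log(1e-6), nb))
  upper <- c(log(20), rep(log(10), length(cls)), rep(log(10), nb))
  bl0 <- if (nb) log(pmax(tree$edge.length, 1e-5)) else numeric(0)

  starts <- list()
  if (model == "one_ratio") {
    for (w0 in c(0.1, 0.5, 1.5))
      starts <- c(starts, list(c(log(2), rep(log(w0), length(cls)), bl0)))
  } else {
    if (is.null(null_fit))
      null_fit <- fit_branch_model(aln, tree, "one_ratio",
                                   codon_frequencies = freqs,
                                   optimize_branch_lengths = optimize_branch_lengths)
    base <- c(log(null_fit$kappa), rep(log(null_fit$omega[[1]]), length(cls)))
    bl_null <- if (nb) log(pmax(null_fit$blens, 1e-6)) else numeric(0)
    starts <- c(starts, list(c(base, bl_null)))
    starts <- c(starts, list(c(log(2), rep(log(0.3), length(cls)), bl0)))
  }
  best <- NULL
  conv <- FALSE
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    fit <- optim(st, make_obj(), method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(maxit = 500, factr = 1e7))
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      conv <- fit$convergence == 0
    }
  }
  om_hat <- setNames(exp(best$par[1 + seq_along(cls)]), cls)
  bl_hat <- if (nb) exp(best$par[1 + length(cls) + seq_len(nb)]) else tree$edge.length
  structure(list(model = model, kappa = exp(best$par[1]), omega = om_hat,
                 lnL = -best$value, convergence = conv, n_eval = obj_count,
                 classes = bct$class, bct = bct, blens = bl_hat,
                 freqs = freqs), class = "codon_model_fit")
}

#' @export
print.codon_model_fit <- function(x, ...) {
  cat(sprintf("<codon_model_fit %s: lnL = %.4f, kappa = %.3f, %d omega class(es)%s>\n",
              x$model, x$lnL, x$kappa, length(x$omega),
              if (x$convergence) "" else ", NOT converged"))
  invisible(x)
}

#' Likelihood-ratio test between nested branch-model fits
#'
#' statistic = 2 (lnL_alt - lnL_null), clipped at zero; df = difference in
#' the number of free omega parameters; p from the chi-square upper tail.
#'
#' @param null_fit,alt_fit `codon_model_fit` objects, null nested in alt.
#' @param tolerance Largest tolerated negative statistic before erroring
#'   (non-nested or failed fits).
#' @return List with `statistic`, `df`, `p`.
#' @export
lrt <- function(null_fit, alt_fit, tolerance = 1e-3) {
  stat <- 2 * (alt_fit$lnL - null_fit$lnL)
  if (stat < -tolerance)
    stopf("2*dlnL = %.6g < 0: fits are not nested or did not converge", stat)
  stat <- max(stat, 0)
  df <- length(alt_fit$omega) - length(null_fit$omega)
  if (df < 1) stopf("alt model has no extra omega parameters")
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Pairwise clade comparisons of free-ratio omegas
#'
#' For each gene, groups per-branch omega estimates from a free-ratio fit by
#' the clade each branch belongs to (a branch belongs to a clade when all
#' its descendant tips do), then runs two-sided Wilcoxon rank-sum tests for
#' each clade pair.
#'
#' @param free_ratio_fits_by_gene Named list of free-ratio `codon_model_fit`
#'   objects (names = genes).
#' @param clade_map Named list: clade name -> tip labels.
#' @return Data frame: gene, clade_a, clade_b, n_a, n_b, W, p, stars.
#' @export
compare_clade_omegas <- function(free_ratio_fits_by_gene, clade_map) {
  out <- NULL
  for (gene in names(free_ratio_fits_by_gene)) {
    fit <- free_ratio_fits_by_gene[[gene]]
    tree <- fit$bct$tree
    desc <- edge_descendant_tips(tree)
    omega_by_clade <- lapply(clade_map, function(tips) {
      missing <- setdiff(tips, tree$tip.label)
      if (length(missing)) stopf("clade tips absent from tree: %s",
                                 paste(missing, collapse = ", "))
      inside <- vapply(desc, function(d) all(d %in% tips), TRUE)
      unname(fit$omega[fit$classes[inside]])
    })
    empty <- names(omega_by_clade)[vapply(omega_by_clade, length, 0L) == 0]
    if (length(empty)) stopf("clade '%s' has no branches in the tree", empty[1])
    cn <- names(clade_map)
    for (i in seq_along(cn)[-length(cn)]) for (j in (i + 1):length(cn)) {
      cg <- compare_groups(omega_by_clade, cn[i], cn[j])
      out <- rbind(out, data.frame(
        gene = gene, clade_a = cn[i], clade_b = cn[j],
        n_a = cg$n[1], n_b = cg$n[2], W = cg$statistic, p = cg$p,
        stars = p_stars(cg$p), stringsAsFactors = FALSE))
    }
  }
  out
}
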