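# Independent oracles and small fixture builders. Everything here is
# deliberately written as plainly as possible (enumeration, brute force)
# and kept separate from the package's own algorithms.

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- NULL
  for (i in 1:n) out <- rbind(out, cbind(i, sub + (sub >= i)))
  out
}

# All outcomes of a single TDRL applied to permutation v.
tdrl_successors <- function(v) {
  n <- length(v)
  keys <- character(0)
  for (mask in 0:(2^n - 1)) {
    left <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    keys <- c(keys, paste(c(v[left], v[!left]), collapse = ","))
  }
  unique(keys)
}

# BFS distances from every permutation of 1..n to the identity under TDRL
# moves (layered backward search on the precomputed successor lists).
tdrl_bfs_distances <- function(n) {
  P <- all_permutations(n)
  keys <- apply(P, 1, paste, collapse = ",")
  succ <- lapply(seq_len(nrow(P)), function(r) tdrl_successors(P[r, ]))
  names(succ) <- keys
  dist <- setNames(rep(Inf, length(keys)), keys)
  idk <- paste(1:n, collapse = ",")
  dist[idk] <- 0
  d <- 0
  repeat {
    pending <- names(dist)[!is.finite(dist)]
    if (!length(pending)) break
    reached <- pending[vapply(pending, function(k)
      any(dist[succ[[k]]] == d), TRUE)]
    if (!length(reached)) break
    d <- d + 1
    dist[reached] <- d
  }
  dist
}

# Common intervals by direct subset enumeration (2^n subsets).
ci_subsets <- function(genes_a, genes_b) {
  n <- length(genes_a)
  pos_a <- seq_len(n)
  pos_b <- match(genes_a, genes_b)
  count <- 0L
  for (mask in 1:(2^n - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    pa <- pos_a[sel]; pb <- pos_b[sel]
    if (max(pa) - min(pa) == sum(sel) - 1 &&
        max(pb) - min(pb) == sum(sel) - 1) count <- count + 1L
  }
  count
}

# Nucleotide diversity by explicit pair loops.
pi_bruteforce <- function(mat) {
  n <- nrow(mat)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    diffs <- 0; comp <- 0
    for (s in seq_len(ncol(mat))) {
      a <- mat[i, s]; b <- mat[j, s]
      if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T")) {
        comp <- comp + 1
        if (a != b) diffs <- diffs + 1
      }
    }
    vals <- c(vals, diffs / comp)
  }
  mean(vals)
}

# NG86 oracle: fresh implementation with recursive pathway enumeration.
ng86_oracle <- function(s1, s2, code_id = "5") {
  gc <- Biostrings::getGeneticCode(code_id)
  codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  c1 <- codons(s1); c2 <- codons(s2)
  syn_sites <- function(cod) {
    tot <- 0
    for (p in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), substr(cod, p, p))) {
      mut <- cod; substr(mut, p, p) <- nt
      if (gc[mut] != "*" && gc[mut] == gc[cod]) tot <- tot + 1 / 3
    }
    tot
  }
  paths <- function(from, to) {
    pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(pos)) return(list(c(sd = 0, nd = 0)))
    out <- list()
    for (p in pos) {
      mid <- from; substr(mid, p, p) <- substr(to, p, p)
      step <- if (gc[from] != "*" && gc[mid] != "*" && gc[from] == gc[mid])
        c(sd = 1, nd = 0) else c(sd = 0, nd = 1)
      legal <- gc[mid] != "*" || length(pos) == 1  # final codon is observed
      for (rest in paths(mid, to)) {
        res <- step + rest
        attr(res, "ok") <- legal && (attr(rest, "ok") %||% TRUE)
        out <- c(out, list(res))
      }
    }
    out
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  S <- 0; Nd <- 0; Sd <- 0; ncod <- 0
  for (k in seq_along(c1)) {
    if (gc[c1[k]] == "*" || gc[c2[k]] == "*") next
    ncod <- ncod + 1
    S <- S + (syn_sites(c1[k]) + syn_sites(c2[k])) / 2
    pl <- paths(c1[k], c2[k])
    ok <- Filter(function(x) isTRUE(attr(x, "ok")), pl)
    use <- if (length(ok)) ok else pl
    avg <- Reduce(`+`, use) / length(use)
    Sd <- Sd + avg["sd"]; Nd <- Nd + avg["nd"]
  }
  N <- 3 * ncod - S
  Nd <- unname(Nd); Sd <- unname(Sd)
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(N = N, S = S, Nd = Nd, Sd = Sd, dN = jc(Nd / N), dS = jc(Sd / S))
}

# GY94 likelihood by exhaustive summation over internal-node states, with
# transition matrices from Matrix::expm (no eigendecomposition, no pruning).
gy94_exhaustive <- function(aln, tree, kappa, omega, freqs) {
  cs <- cnidmito:::code_structure(aln$genetic_code_id)
  Q <- cnidmito:::gy94_matrix(kappa, omega, freqs, cs)
  mu <- -sum(freqs * diag(Q))
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q / mu * tree$edge.length[e])))
  ncod <- length(cs$codons)
  ntip <- ape::Ntip(tree)
  states <- matrix(match(aln$codons, cs$codons), nrow = nrow(aln$codons))
  tipidx <- match(tree$tip.label, aln$ids)
  nint <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(seq_len(ncod)), nint)))
  total <- 0
  for (site in seq_len(ncol(states))) {
    node_state <- function(nd) {
      if (nd <= ntip) rep(states[tipidx[nd], site], nrow(grid))
      else grid[, nd - ntip]
    }
    pr <- freqs[grid[, 1]]
    for (e in seq_len(nrow(tree$edge))) {
      a <- node_state(tree$edge[e, 1]); b <- node_state(tree$edge[e, 2])
      pr <- pr * P[[e]][cbind(a, b)]
    }
    total <- total + log(sum(pr))
  }
  total
}

# Signed adjacency set of a circular signed order (independent encoding:
# a normalized "x>y" string per adjacency, reflection-invariant).
adjacency_oracle <- function(so) {
  g <- so$genes; s <- so$signs
  n <- length(g)
  out <- character(n)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1 else k + 1
    a <- paste0(if (s[k] > 0) "+" else "-", g[k])
    b <- paste0(if (s[k2] > 0) "+" else "-", g[k2])
    flip <- function(x) paste0(if (substr(x, 1, 1) == "+") "-" else "+",
                               substr(x, 2, nchar(x)))
    f1 <- paste(a, b, sep = ">")
    f2 <- paste(flip(b), flip(a), sep = ">")
    out[k] <- min(f1, f2)
  }
  sort(out)
}

adj_dist_oracle <- function(o1, o2) {
  a1 <- adjacency_oracle(o1); a2 <- adjacency_oracle(o2)
  length(setdiff(a1, a2)) + length(setdiff(a2, a1))
}

# Restricted Sankoff: minimum total adjacency distance over all assignments
# of `candidates` (signed orders) to the internal nodes of `tree`, leaves
# fixed at `leaf_orders`.
sankoff_restricted <- function(tree, leaf_orders, candidates) {
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  ncand <- length(candidates)
  # pairwise distances
  leaf_list <- lapply(tree$tip.label, function(tp) leaf_orders[[tp]])
  d_cc <- outer(seq_len(ncand), seq_len(ncand),
                Vectorize(function(i, j) adj_dist_oracle(candidates[[i]], candidates[[j]])))
  d_cl <- outer(seq_len(ncand), seq_len(ntip),
                Vectorize(function(i, j) adj_dist_oracle(candidates[[i]], leaf_list[[j]])))
  grid <- as.matrix(expand.grid(rep(list(seq_len(ncand)), nint)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    cost <- 0
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; c2 <- tree$edge[e, 2]
      pi_ <- grid[r, p - ntip]
      cost <- cost + if (c2 <= ntip) d_cl[pi_, c2] else d_cc[pi_, grid[r, c2 - ntip]]
    }
    if (cost < best) best <- cost
  }
  best
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
wilcox_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  combs <- combn(length(pooled), n)
  U_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  Us <- apply(combs, 2, function(idx)
    sum(rank(pooled)[idx]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(Us <= U_obs), mean(Us >= U_obs)))
}

# Random signed gene order over k letters.
random_signed_order <- function(k, letters_pool = LETTERS) {
  signed_gene_order(sample(letters_pool[seq_len(k)]),
                    sample(c(-1L, 1L), k, replace = TRUE))
}

# A small GenBank flat file written to `path`; 2 records.
write_genbank_fixture <- function(path) {
  seq1 <- paste(rep("acgt", 25), collapse = "")   # 100 bp
  fmt_origin <- function(s) {
    rows <- substring(s, seq(1, nchar(s), 60), pmin(seq(60, nchar(s) + 59, 60), nchar(s)))
    paste0("        1 ", rows)
  }
  lines <- c(
    "LOCUS       TEST1                100 bp    DNA     circular CON 01-JAN-2020",
    "ACCESSION   TEST1",
    "  ORGANISM  Testus firstus",
    "FEATURES             Location/Qualifiers",
    "     CDS             complement(10..20)",
    "                     /gene=\"COI\"",
    "     rRNA            join(95..100,1..5)",
    "                     /product=\"16S ribosomal RNA\"",
    "ORIGIN      ",
    fmt_origin(seq1),
    "//",
    "LOCUS       TEST2                 63 bp    DNA     linear   CON 01-JAN-2020",
    "ACCESSION   TEST2",
    "  ORGANISM  Testus secundus",
    "FEATURES             Location/Qualifiers",
    "     CDS             5..34",
    "                     /gene=\"ND4L\"",
    "ORIGIN      ",
    fmt_origin(paste(rep("gattaca", 9), collapse = "")),
    "//")
  writeLines(lines, path)
  path
}
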