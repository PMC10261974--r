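# Ancestral gene-order reconstruction on a fixed tree: every signed
# adjacency (including the circular closing adjacency) is a binary
# presence/absence character scored with Fitch passes; each internal node's
# selected adjacencies are greedily assembled into a single valid circular
# signed tour (highest leaf support first), and each edge is annotated with
# an inferred rearrangement scenario.

# Extremity naming: gene "X" has tail "X.t" and head "X.h"; a gene on the
# plus strand is traversed tail -> head.
adjacency_keys <- function(order) {
  g <- order$genes; s <- order$signs
  n <- length(g)
  exit <- ifelse(s > 0, paste0(g, ".h"), paste0(g, ".t"))
  nxt <- c(2:n, 1)
  enter <- ifelse(s[nxt] > 0, paste0(g[nxt], ".t"), paste0(g[nxt], ".h"))
  vapply(seq_len(n), function(i) {
    pair <- sort(c(exit[i], enter[i]))
    paste(pair, collapse = "|")
  }, "")
}

# Greedy assembly of adjacencies into one circular tour over `genes`.
# Candidates are tried by decreasing support then key; an adjacency is taken
# when both extremities are free and it does not close a cycle early. Any
# remaining open path ends are joined deterministically. Returns the order
# plus a `clean` flag (TRUE when the candidate set itself formed the tour).
assemble_tour <- function(candidates, support, genes) {
  n <- length(genes)
  ord <- order(-support[candidates], candidates)
  candidates <- candidates[ord]
  parent <- seq_len(n)                        # union-find over genes

  findi <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  gene_id <- setNames(seq_len(n), genes)
  used_ext <- character(0)
  taken <- character(0)
  clean <- TRUE
  for (key in candidates) {
    ext <- strsplit(key, "|", fixed = TRUE)[[1]]
    if (any(ext %in% used_ext)) { clean <- FALSE; next }
    g1 <- gene_id[[sub("\\.[th]$", "", ext[1])]]
    g2 <- gene_id[[sub("\\.[th]$", "", ext[2])]]
    r1 <- findi(g1); r2 <- findi(g2)
    if (r1 == r2 && length(taken) < n - 1) { clean <- FALSE; next }
    parent[r1] <- r2
    used_ext <- c(used_ext, ext)
    taken <- c(taken, key)
    if (length(taken) == n) break
  }
  # complete with deterministic joins if the tour is still open
  while (length(taken) < n) {
    clean <- FALSE
    free <- sort(setdiff(c(paste0(genes, ".t"), paste0(genes, ".h")), used_ext))
    picked <- NULL
    for (a in free) for (b in free) {
      if (a >= b) next
      ga <- gene_id[[sub("\\.[th]$", "", a)]]
      gb <- gene_id[[sub("\\.[th]$", "", b)]]
      if (ga == gb) next
      ra <- findi(ga); rb <- findi(gb)
      if (ra == rb && length(taken) < n - 1) next
      picked <- c(a, b); break
    }
    if (is.null(picked)) {
      # final closing adjacency between the two remaining extremities
      picked <- free[1:2]
    }
    parent[findi(gene_id[[sub("\\.[th]$", "", picked[1])]])] <-
      findi(gene_id[[sub("\\.[th]$", "", picked[2])]])
    used_ext <- c(used_ext, picked)
    taken <- c(taken, paste(sort(picked), collapse = "|"))
  }
  # decode the tour into a signed order
  link <- new.env(parent = emptyenv())
  for (key in taken) {
    ext <- strsplit(key, "|", fixed = TRUE)[[1]]
    assign(ext[1], ext[2], envir = link)
    assign(ext[2], ext[1], envir = link)
  }
  g <- genes[1]; s <- 1L
  out_genes <- character(0); out_signs <- integer(0)
  for (step in seq_len(n)) {
    out_genes <- c(out_genes, g)
    out_signs <- c(out_signs, s)
    exit_ext <- if (s > 0) paste0(g, ".h") else paste0(g, ".t")
    nxt <- get(exit_ext, envir = link)
    g <- sub("\\.[th]$", "", nxt)
    s <- if (grepl("\\.t$", nxt)) 1L else -1L
  }
  list(order = signed_gene_order(out_genes, out_signs), clean = clean)
}

#' Ancestral gene orders by adjacency parsimony
#'
#' Scores every signed adjacency seen in the leaves as a binary character
#' with Fitch bottom-up/top-down passes over the (binary) tree, then
#' assembles each internal node's selected adjacency set into a valid
#' circular signed order, preferring adjacencies with higher leaf support
#' (ties broken lexicographically). Each edge is annotated with an inferred
#' rearrangement scenario and the adjacency (breakpoint-like) distance
#' between its endpoint orders. Multifurcations are resolved into binary
#' nodes with zero-length branches (logged).
#'
#' @param tree Rooted `ape::phylo`; tips must name entries of `leaf_orders`.
#' @param leaf_orders Named list of [signed_gene_order()], one per tip, all
#'   over the same gene set.
#' @return List with `tree` (possibly dichotomised), `node_orders` (list
#'   indexed by node number, tips included), `edge_scenarios`,
#'   `edge_adjacency_distance`, `total_events`, `event_counts`,
#'   `fitch_cost` (total adjacency changes from the Fitch passes),
#'   `assignment_cost` (sum of per-edge adjacency distances), and
#'   `unresolved` (node numbers whose adjacency set needed repair).
#' @export
ancestral_orders <- function(tree, leaf_orders) {
  missing <- setdiff(tree$tip.label, names(leaf_orders))
  if (length(missing)) stopf("no order for tips: %s", paste(missing, collapse = ", "))
  if (!ape::is.binary(tree)) {
    cm_log$add("multifurcating tree dichotomised with zero-length branches")
    tree <- ape::multi2di(tree, random = FALSE)
    if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  genes <- sort(leaf_orders[[1]]$genes)
  anchor <- default_anchor(genes)
  leaf_orders <- lapply(leaf_orders, function(o) {
    if (!setequal(o$genes, genes)) stopf("leaf orders differ in gene content")
    canonicalize(o, anchor)
  })
  leaf_adj <- lapply(tree$tip.label, function(tp) adjacency_keys(leaf_orders[[tp]]))
  all_keys <- sort(unique(unlist(leaf_adj)))
  na <- length(all_keys)
  support <- setNames(colSums(do.call(rbind, lapply(leaf_adj, function(a) all_keys %in% a))),
                      all_keys)

  # Fitch sets as 2-bit masks: 1 = absent, 2 = present
  sets <- matrix(0L, ntip + nnode, na)
  for (i in seq_len(ntip))
    sets[i, ] <- ifelse(all_keys %in% leaf_adj[[i]], 2L, 1L)
  po <- ape::reorder.phylo(tree, "postorder")
  fitch_cost <- 0L
  kids <- split(po$edge[, 2], po$edge[, 1])
  for (node in unique(po$edge[, 1])) {
    ch <- kids[[as.character(node)]]
    acc <- sets[ch[1], ]
    for (c2 in ch[-1]) {
      inter <- bitwAnd(acc, sets[c2, ])
      uni <- bitwOr(acc, sets[c2, ])
      fitch_cost <- fitch_cost + sum(inter == 0L)
      acc <- ifelse(inter != 0L, inter, uni)
    }
    sets[node, ] <- acc
  }
  # top-down assignment
  state <- matrix(NA_integer_, ntip + nnode, na)
  root <- ntip + 1L
  root_set <- sets[root, ]
  maj <- support[all_keys] >= ntip / 2
  state[root, ] <- ifelse(root_set == 3L, ifelse(maj, 2L, 1L), root_set)
  for (e in rev(seq_len(nrow(po$edge)))) {   # preorder
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    if (child <= ntip) next
    cs <- sets[child, ]
    ps <- state[parent, ]
    state[child, ] <- ifelse(bitwAnd(cs, ps) != 0L, ps,
                             ifelse(cs == 3L, ps, cs))
  }

  node_orders <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) node_orders[[i]] <- leaf_orders[[tree$tip.label[i]]]
  unresolved <- integer(0)
  for (node in (ntip + 1):(ntip + nnode)) {
    cand <- all_keys[state[node, ] == 2L]
    res <- assemble_tour(cand, support, genes)
    if (!res$clean) unresolved <- c(unresolved, node)
    node_orders[[node]] <- canonicalize(res$order, anchor)
  }

  edge_scenarios <- vector("list", nrow(tree$edge))
  edge_adj <- numeric(nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c2 <- tree$edge[e, 2]
    edge_scenarios[[e]] <- infer_scenario(node_orders[[p]], node_orders[[c2]])
    a1 <- adjacency_keys(node_orders[[p]]); a2 <- adjacency_keys(node_orders[[c2]])
    edge_adj[e] <- length(setdiff(a1, a2)) + length(setdiff(a2, a1))
  }
  types <- unlist(lapply(edge_scenarios, function(s) vapply(s$events, `[[`, "", "type")))
  event_counts <- vapply(c("inversion", "transposition", "reverse_transposition", "TDRL"),
                         function(t) sum(types == t), 0L)
  list(tree = tree, node_orders = node_orders, edge_scenarios = edge_scenarios,
       edge_adjacency_distance = edge_adj,
       total_events = sum(vapply(edge_scenarios, function(s) length(s$events), 0L)),
       event_counts = event_counts,
       fitch_cost = fitch_cost,
       assignment_cost = sum(edge_adj),
       unresolved = unresolved)
}

#' Build a tree from a gene-order distance matrix
#'
#' Neighbor-joining over a pattern distance matrix (see
#' [pattern_distance_matrix()]); leaves are pattern ids.
#'
#' @param matrix Symmetric distance matrix with dimnames.
#' @return An `ape::phylo`.
#' @export
gene_order_tree <- function(matrix) {
  nj_tree(matrix)
}
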