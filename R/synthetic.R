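# Seeded mitogenome-evolution simulator. A Yule tree is decorated with
# rearrangement events (Poisson per edge) acting on a 15-gene signed root
# order, and with codon sequences evolved by Gillespie simulation under the
# same GY94 rate matrix the selection module fits, so every analysis stage
# has ground truth: the tree, the per-edge event log, per-branch omega, and
# the root sequences.

# Fixed 15-gene reference order used as the simulation root (all plus
# strand; a plausible cnidarian-like arrangement, synthetic by design).
REFERENCE_ORDER <- c("COX1", "rrnL", "NAD2", "NAD5", "NAD4", "COX2", "ATP8",
                     "ATP6", "COX3", "rrnS", "NAD6", "NAD3", "NAD4L", "NAD1",
                     "CYTB")

DEFAULT_CODON_LENGTHS <- c(ATP6 = 232, ATP8 = 70, COX1 = 517, COX2 = 250,
                           COX3 = 261, CYTB = 380, NAD1 = 315, NAD2 = 450,
                           NAD3 = 117, NAD4 = 480, NAD4L = 100, NAD5 = 600,
                           NAD6 = 190)

#' Build a simulation configuration
#'
#' Defaults describe a small but realistic cnidarian-like study: 12 leaves,
#' Yule topology scaled to a mean root-to-tip depth of 0.3 expected
#' substitutions per codon, strongly purifying selection (omega 0.1),
#' moderate transition bias (kappa 2), A+T fraction 0.62, and a gene order
#' evolving by inversion, transposition, reverse transposition and TDRL.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param birth_rate Yule speciation rate.
#' @param tree_depth Mean root-to-tip path length after rescaling (expected
#'   substitutions per codon site).
#' @param event_rates Named rates per unit branch length for `inversion`,
#'   `transposition`, `reverse_transposition`, `TDRL`.
#' @param root_order Character vector of the 15-gene root arrangement.
#' @param kappa Transition/transversion ratio of the codon model.
#' @param omega Named numeric of omega by branch class. A single unnamed
#'   value means one class for the whole tree; `c(background=, foreground=)`
#'   needs `foreground`.
#' @param foreground Tip labels spanning the foreground clade (two-ratio
#'   simulations); ignored for a single omega.
#' @param theta_at Stationary A+T fraction used to build F3x4-style codon
#'   frequencies (0 < theta_at < 1).
#' @param codon_lengths Named integer vector: codon count per simulated
#'   protein-coding gene.
#' @param rrna_lengths Lengths (nt) of the two rRNAs laid into genomes.
#' @param spacer_length Intergenic spacer length (nt).
#' @param genetic_code_id Genetic code (default invertebrate mitochondrial).
#' @param seed Mandatory integer seed; the single RNG stream for the run.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_leaves = 12, birth_rate = 1, tree_depth = 0.3,
                              event_rates = c(inversion = 1, transposition = 0.5,
                                              reverse_transposition = 0.25, TDRL = 0.25),
                              root_order = REFERENCE_ORDER,
                              kappa = 2, omega = c(omega = 0.1), foreground = NULL,
                              theta_at = 0.62,
                              codon_lengths = DEFAULT_CODON_LENGTHS,
                              rrna_lengths = c(rrnS = 800, rrnL = 1600),
                              spacer_length = 20,
                              genetic_code_id = "5", seed) {
  if (missing(seed)) stopf("simulation_config requires an explicit seed")
  stopifnot(n_leaves >= 2, birth_rate > 0, tree_depth > 0,
            all(event_rates >= 0), theta_at > 0, theta_at < 1,
            all(codon_lengths >= 2), spacer_length >= 0)
  req <- c("inversion", "transposition", "reverse_transposition", "TDRL")
  if (!all(req %in% names(event_rates)))
    stopf("event_rates must name: %s", paste(req, collapse = ", "))
  uncovered <- setdiff(root_order, c(names(codon_lengths), names(rrna_lengths)))
  if (length(uncovered))
    stopf("root_order genes without a sequence length: %s",
          paste(uncovered, collapse = ", "))
  if (is.null(names(omega))) names(omega) <- if (length(omega) == 1) "omega" else
    stopf("multi-class omega must be named")
  structure(list(n_leaves = as.integer(n_leaves), birth_rate = birth_rate,
                 tree_depth = tree_depth, event_rates = event_rates[req],
                 root_order = root_order, kappa = kappa, omega = omega,
                 foreground = foreground, theta_at = theta_at,
                 codon_lengths = codon_lengths, rrna_lengths = rrna_lengths,
                 spacer_length = as.integer(spacer_length),
                 genetic_code_id = as.character(genetic_code_id),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a Yule tree
#'
#' Pure-birth tree with exponential waiting times, rescaled so the mean
#' root-to-tip path equals `tree_depth`. Uses the configuration seed, so a
#' fixed config gives an identical tree.
#'
#' @param config A [simulation_config()].
#' @return `ape::phylo` with `n_leaves` tips labelled t1..tn.
#' @export
simulate_tree <- function(config) {
  set.seed(config$seed)
  tr <- ape::rphylo(config$n_leaves, birth = config$birth_rate, death = 0)
  depths <- ape::node.depth.edgelength(tr)[seq_len(config$n_leaves)]
  tr$edge.length <- tr$edge.length * config$tree_depth / mean(depths)
  tr
}

# F3x4-style codon frequencies from a single A+T fraction.
theta_codon_frequencies <- function(theta_at, genetic_code_id = "5") {
  p <- c(A = theta_at / 2, C = (1 - theta_at) / 2,
         G = (1 - theta_at) / 2, T = theta_at / 2)
  sc <- sense_codons(genetic_code_id)
  f <- vapply(strsplit(sc, ""), function(ch) prod(p[ch]), numeric(1))
  setNames(f / sum(f), sc)
}

random_event <- function(n, type) {
  if (type == "TDRL")
    return(rearrangement_event("TDRL",
                               partition = sample(c("L", "R"), n, replace = TRUE)))
  i <- sample.int(n, 1); j <- sample.int(n, 1)
  block <- sort(c(i, j))
  if (type == "inversion")
    return(rearrangement_event("inversion", block = block))
  len <- block[2] - block[1] + 1
  if (len == n) block[2] <- block[2] - 1  # a moved block must leave a remainder
  len <- block[2] - block[1] + 1
  # dest == block start is the identity for transpositions and a pure
  # inversion for reverse transpositions; draw a genuinely moving position
  dest <- sample.int(n - len + 1, 1)
  if (dest == block[1])
    dest <- if (dest == n - len + 1) max(1, dest - 1) else dest + 1
  rearrangement_event(type, block = block, dest = dest)
}

#' Evolve gene orders along a tree
#'
#' Each edge receives Poisson(rate x length) events per type; event
#' parameters are drawn uniformly and applied in shuffled order via
#' [apply_event()]. The full per-edge log is retained; replaying it from
#' the root order reproduces every node order exactly.
#'
#' @param tree `ape::phylo` (from [simulate_tree()]).
#' @param config A [simulation_config()].
#' @return List with `leaf_orders` (named by tip), `node_orders` (by node
#'   number), `edge_events` (list per `tree$edge` row), `root_order`.
#' @export
evolve_gene_orders <- function(tree, config) {
  n <- length(config$root_order)
  root_so <- signed_gene_order(config$root_order, record_id = "root")
  ntip <- ape::Ntip(tree)
  node_orders <- vector("list", ntip + tree$Nnode)
  node_orders[[ntip + 1L]] <- root_so
  edge_events <- vector("list", nrow(tree$edge))
  po <- ape::reorder.phylo(tree, "postorder")
  pre <- rev(seq_len(nrow(po$edge)))
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  for (e in pre) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    len <- po$edge.length[e]
    counts <- rpois(4, config$event_rates * len)
    types <- rep(names(config$event_rates), counts)
    if (length(types) > 1) types <- sample(types)
    cur <- node_orders[[parent]]
    evs <- list()
    for (tp in types) {
      ev <- random_event(n, tp)
      cur <- apply_event(cur, ev)
      evs <- c(evs, list(ev))
    }
    node_orders[[child]] <- cur
    edge_events[[match(paste(parent, child), edge_key)]] <- evs
  }
  leaf_orders <- setNames(node_orders[seq_len(ntip)], tree$tip.label)
  for (tp in tree$tip.label) leaf_orders[[tp]]$record_id <- tp
  list(leaf_orders = leaf_orders, node_orders = node_orders,
       edge_events = edge_events, root_order = root_so)
}

# Gillespie simulation of one branch for a vector of codon state indices,
# vectorised across codons: each round draws exponential waiting times for
# all still-active codons and jumps those whose event falls inside the
# remaining time, sampling targets from the embedded jump chain.
gillespie_branch <- function(states, t, Qs) {
  rate_out <- -diag(Qs)
  jump <- Qs / rate_out
  diag(jump) <- 0
  jumpcum <- t(apply(jump, 1, cumsum))
  syn_map <- attr(Qs, "syn_map")
  nsub_syn <- 0L; nsub_nonsyn <- 0L
  rem <- rep(t, length(states))
  active <- which(rate_out[states] > 0)
  while (length(active)) {
    w <- rexp(length(active), rate_out[states[active]])
    hit <- w < rem[active]
    idx <- active[hit]
    if (length(idx)) {
      rem[idx] <- rem[idx] - w[hit]
      u <- runif(length(idx))
      old <- states[idx]
      new <- rowSums(jumpcum[old, , drop = FALSE] < u) + 1L
      sy <- syn_map[cbind(old, new)]
      nsub_syn <- nsub_syn + sum(sy)
      nsub_nonsyn <- nsub_nonsyn + sum(!sy)
      states[idx] <- new
    }
    active <- idx[rate_out[states[idx]] > 0]
  }
  attr(states, "nsyn") <- as.integer(nsub_syn)
  attr(states, "nnonsyn") <- as.integer(nsub_nonsyn)
  states
}

#' Evolve codon sequences along a tree
#'
#' Root codons are drawn from the stationary frequencies; substitution
#' along each branch is simulated with the Gillespie algorithm under the
#' same GY94 rate matrix used by [gy94_loglik()] (scaled so the first
#' omega class has mean rate one), with the branch's omega chosen by its
#' class. No indels.
#'
#' @param tree `ape::phylo`.
#' @param config A [simulation_config()].
#' @return List with `alignments` (named list of [codon_alignment()], one
#'   per gene), `edge_substitutions` (per edge: synonymous and
#'   nonsynonymous counts summed over genes), `bct` (the branch-class tree
#'   used), `frequencies`.
#' @export
evolve_codon_sequences <- function(tree, config) {
  cs <- code_structure(config$genetic_code_id)
  freqs <- theta_codon_frequencies(config$theta_at, config$genetic_code_id)
  omega <- config$omega
  bct <- if (length(omega) == 1) {
    b <- branch_class_tree(tree, "one_ratio")
    b$class <- rep(names(omega), length(b$class))
    b
  } else {
    if (is.null(config$foreground)) stopf("multi-class omega needs foreground tips")
    b <- branch_class_tree(tree, "two_ratio", foreground_set = config$foreground)
    b
  }
  if (!all(bct$class %in% names(omega)))
    stopf("omega missing classes: %s",
          paste(setdiff(unique(bct$class), names(omega)), collapse = ", "))
  mu <- -sum(freqs * diag(gy94_matrix(config$kappa, omega[[1]], freqs, cs)))
  Qs_by_class <- lapply(unique(bct$class), function(cl) {
    Q <- gy94_matrix(config$kappa, omega[[cl]], freqs, cs) / mu
    syn_map <- matrix(FALSE, length(cs$codons), length(cs$codons))
    for (k in 1:9) {
      j <- cs$tgt[, k]; ok <- !is.na(j)
      syn_map[cbind(which(ok), j[ok])] <- cs$syn[ok, k]
    }
    attr(Q, "syn_map") <- syn_map
    Q
  })
  names(Qs_by_class) <- unique(bct$class)

  ntip <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  po_key <- paste(po$edge[, 1], po$edge[, 2])
  class_po <- bct$class[match(po_key, edge_key)]
  genes <- names(config$codon_lengths)
  edge_sub <- matrix(0L, nrow(tree$edge), 2,
                     dimnames = list(NULL, c("syn", "nonsyn")))
  alignments <- list()
  for (g in genes) {
    L <- config$codon_lengths[[g]]
    node_states <- vector("list", ntip + tree$Nnode)
    node_states[[ntip + 1L]] <- sample.int(length(cs$codons), L, replace = TRUE,
                                           prob = freqs)
    for (e in rev(seq_len(nrow(po$edge)))) {
      parent <- po$edge[e, 1]; child <- po$edge[e, 2]
      st <- gillespie_branch(node_states[[parent]], po$edge.length[e],
                             Qs_by_class[[class_po[e]]])
      row <- match(po_key[e], edge_key)
      edge_sub[row, "syn"] <- edge_sub[row, "syn"] + attr(st, "nsyn")
      edge_sub[row, "nonsyn"] <- edge_sub[row, "nonsyn"] + attr(st, "nnonsyn")
      attributes(st) <- NULL
      node_states[[child]] <- st
    }
    seqs <- vapply(seq_len(ntip), function(i)
      paste(cs$codons[node_states[[i]]], collapse = ""), "")
    names(seqs) <- tree$tip.label
    alignments[[g]] <- codon_alignment(seqs, gene = g,
                                       genetic_code_id = config$genetic_code_id)
  }
  list(alignments = alignments, edge_substitutions = edge_sub, bct = bct,
       frequencies = freqs)
}

random_at_sequence <- function(len, theta_at) {
  p <- c(theta_at / 2, (1 - theta_at) / 2, (1 - theta_at) / 2, theta_at / 2)
  paste(sample(NUCS, len, replace = TRUE, prob = p), collapse = "")
}

#' Run the full simulator
#'
#' Seeds the RNG once, simulates the tree, the gene orders (with event
#' log), the codon sequences, and a pair of clonal rRNA sequences, then
#' assembles one circular genome record per leaf with genes laid out in the
#' leaf's order (minus-strand genes reverse-complemented) separated by
#' AT-biased spacers.
#'
#' @param config A [simulation_config()].
#' @return List with `records` (list of [mitogenome_record()]),
#'   `alignments`, `tree`, `truth` (a `simulation_truth`: tree newick,
#'   per-edge event log, per-branch omega class and value, edge
#'   substitution counts, seed, config echo).
#' @export
simulate_mitogenomes <- function(config) {
  tree <- simulate_tree(config)            # seeds the stream
  go <- evolve_gene_orders(tree, config)
  cseq <- evolve_codon_sequences(tree, config)
  rrna <- lapply(config$rrna_lengths, function(L)
    random_at_sequence(L, config$theta_at))

  ntip <- ape::Ntip(tree)
  records <- lapply(seq_len(ntip), function(i) {
    tp <- tree$tip.label[i]
    so <- go$leaf_orders[[tp]]
    parts <- character(0); feats <- list(); pos <- 0L
    for (k in seq_along(so$genes)) {
      g <- so$genes[k]
      s <- if (g %in% names(cseq_genes <- config$codon_lengths)) {
        seqs <- cseq$alignments[[g]]
        paste(seqs$codons[match(tp, seqs$ids), ], collapse = "")
      } else rrna[[g]]
      strand <- if (so$signs[k] < 0) "-" else "+"
      emit <- if (strand == "-") revcomp(s) else s
      feats[[k]] <- gene_feature(raw_name = g, gene = g,
                                 kind = if (g %in% CANONICAL_PCGS) "PCG" else "rRNA",
                                 strand = strand, start = pos,
                                 end = pos + nchar(emit))
      parts <- c(parts, emit)
      pos <- pos + nchar(emit)
      if (config$spacer_length > 0) {
        parts <- c(parts, random_at_sequence(config$spacer_length, config$theta_at))
        pos <- pos + config$spacer_length
      }
    }
    mitogenome_record(record_id = tp, sequence = paste(parts, collapse = ""),
                      features = feats, taxon = tp, topology = "circular")
  })
  truth <- structure(list(
    newick = ape::write.tree(tree),
    edge_events = go$edge_events,
    node_orders = go$node_orders,
    root_order = go$root_order,
    branch_class = cseq$bct$class,
    omega = config$omega,
    edge_substitutions = cseq$edge_substitutions,
    seed = config$seed,
    config = config), class = "simulation_truth")
  list(records = records, alignments = cseq$alignments, tree = tree,
       leaf_orders = go$leaf_orders, truth = truth)
}

#' Emit simulated records to files
#'
#' Writes a multi-FASTA of genome sequences, the feature-table TSV, a
#' taxonomy TSV (clades from the root split of the tree), the tree newick,
#' and the ground truth as JSON.
#'
#' @param sim Result of [simulate_mitogenomes()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
emit_records <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genomes.fasta")
  seqs <- Biostrings::DNAStringSet(vapply(sim$records, `[[`, "", "sequence"))
  names(seqs) <- vapply(sim$records, `[[`, "", "record_id")
  Biostrings::writeXStringSet(seqs, fasta)
  feat <- file.path(dir, "features.tsv")
  write_feature_table(sim$records, feat)
  tree_path <- file.path(dir, "tree.nwk")
  write_newick(sim$tree, tree_path)
  # taxonomy: two clades from the root split
  root <- ape::Ntip(sim$tree) + 1L
  kids <- sim$tree$edge[sim$tree$edge[, 1] == root, 2]
  ntip <- ape::Ntip(sim$tree)
  cladeA <- if (kids[1] <= ntip) sim$tree$tip.label[kids[1]] else
    ape::extract.clade(sim$tree, kids[1])$tip.label
  tax <- data.frame(record_id = sim$tree$tip.label,
                    taxon = sim$tree$tip.label,
                    class = ifelse(sim$tree$tip.label %in% cladeA, "cladeA", "cladeB"),
                    subclass = "", order = "", stringsAsFactors = FALSE)
  tax_path <- file.path(dir, "taxonomy.tsv")
  write_table(tax, tax_path)
  truth_path <- file.path(dir, "truth.json")
  tr <- sim$truth
  serial <- list(
    newick = tr$newick,
    seed = tr$seed,
    omega = as.list(tr$omega),
    branch_class = tr$branch_class,
    root_order = order_string(tr$root_order),
    leaf_orders = lapply(sim$leaf_orders, order_string),
    edge_events = lapply(tr$edge_events, function(evs)
      lapply(evs, function(e) list(type = e$type, block = e$block,
                                   dest = e$dest, partition = e$partition))),
    edge_substitutions = as.data.frame(tr$edge_substitutions))
  jsonlite::write_json(serial, truth_path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  c(fasta = fasta, features = feat, tree = tree_path, taxonomy = tax_path,
    truth = truth_path)
}
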