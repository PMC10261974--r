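small_cfg <- function(seed, ...) {
  simulation_config(n_leaves = 6, codon_lengths = c(COX1 = 80, NAD5 = 60),
                    root_order = c("COX1", "rrnL", "NAD5", "rrnS"),
                    rrna_lengths = c(rrnS = 120, rrnL = 200),
                    seed = seed, ...)
}

test_that("the simulator is fully deterministic under a fixed seed", {
  s1 <- simulate_mitogenomes(small_cfg(101))
  s2 <- simulate_mitogenomes(small_cfg(101))
  expect_equal(vapply(s1$records, `[[`, "", "sequence"),
               vapply(s2$records, `[[`, "", "sequence"))
  expect_equal(lapply(s1$leaf_orders, order_string),
               lapply(s2$leaf_orders, order_string))
  expect_equal(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  s3 <- simulate_mitogenomes(small_cfg(102))
  expect_false(identical(vapply(s1$records, `[[`, "", "sequence"),
                         vapply(s3$records, `[[`, "", "sequence")))
})

test_that("zero event rates leave every leaf at the root order; logs replay exactly", {
  quiet <- small_cfg(55, event_rates = c(inversion = 0, transposition = 0,
                                         reverse_transposition = 0, TDRL = 0))
  simq <- simulate_mitogenomes(quiet)
  for (o in simq$leaf_orders)
    expect_equal(order_string(canonicalize(o)),
                 order_string(canonicalize(simq$truth$root_order)))

  busy <- small_cfg(56, event_rates = c(inversion = 3, transposition = 2,
                                        reverse_transposition = 1, TDRL = 2))
  simb <- simulate_mitogenomes(busy)
  tree <- simb$tree
  # replay the event log from the root down every path
  node_orders <- vector("list", ape::Ntip(tree) + tree$Nnode)
  node_orders[[ape::Ntip(tree) + 1]] <- simb$truth$root_order
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in rev(seq_len(nrow(po$edge)))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    row <- match(paste(parent, child),
                 paste(tree$edge[, 1], tree$edge[, 2]))
    evs <- simb$truth$edge_events[[row]]
    if (is.null(evs)) evs <- list()
    node_orders[[child]] <- replay_events(node_orders[[parent]], evs)
  }
  for (i in seq_len(ape::Ntip(tree)))
    expect_equal(order_string(node_orders[[i]]),
                 order_string(simb$leaf_orders[[tree$tip.label[i]]]))
})

test_that("every emitted genome contains each simulated gene exactly once", {
  sim <- simulate_mitogenomes(small_cfg(77))
  for (r in sim$records) {
    genes <- vapply(r$features, `[[`, "", "gene")
    expect_setequal(genes, c("COX1", "rrnL", "NAD5", "rrnS"))
    expect_equal(anyDuplicated(genes), 0L)
  }
})

test_that("omega zero forbids nonsynonymous substitutions", {
  cfg <- small_cfg(88, omega = c(omega = 0))
  tree <- simulate_tree(cfg)
  cs <- evolve_codon_sequences(tree, cfg)
  expect_equal(sum(cs$edge_substitutions[, "nonsyn"]), 0L)
  expect_gt(sum(cs$edge_substitutions[, "syn"]), 0L)
})

test_that("emitted A+T content rises with theta_at", {
  at <- vapply(c(0.3, 0.5, 0.7), function(th) {
    sim <- simulate_mitogenomes(small_cfg(99, theta_at = th))
    mean(vapply(sim$records, function(r) base_composition(r$sequence)$at_percent, 0))
  }, 0)
  expect_true(all(diff(at) > 0))
})

test_that("emitted files round-trip through the readers with orders preserved", {
  sim <- simulate_mitogenomes(small_cfg(111))
  dir <- tempfile()
  paths <- emit_records(sim, dir)
  expect_true(all(file.exists(paths)))
  recs <- read_feature_table(paths["fasta"], paths["features"],
                             taxonomy = paths["taxonomy"])
  expect_length(recs, 6)
  for (r in recs) {
    o <- extract_gene_order(r, alphabet = c("COX1", "rrnL", "NAD5", "rrnS"))
    expect_equal(order_string(o),
                 order_string(canonicalize(sim$leaf_orders[[r$record_id]])))
  }
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(truth$seed, 111L)
  expect_equal(ape::write.tree(sim$tree), truth$newick)
})

test_that("shallow-pair NG86 estimates approach the simulating omega", {
  cfg <- simulation_config(n_leaves = 2, codon_lengths = c(G1 = 6000),
                           root_order = c("G1", "rrnS", "rrnL"),
                           tree_depth = 0.05, omega = c(omega = 0.3), seed = 121)
  tree <- simulate_tree(cfg)
  cs <- evolve_codon_sequences(tree, cfg)
  seqs <- apply(cs$alignments$G1$codons, 1, paste, collapse = "")
  r <- ng86_pairwise(seqs[1], seqs[2])
  expect_equal(r$omega, 0.3, tolerance = 0.25)
})
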