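ref15 <- cnidmito:::REFERENCE_ORDER

test_that("canonical form is idempotent and invariant to rotation and reflection", {
  set.seed(17)
  for (i in 1:25) {
    so <- signed_gene_order(sample(ref15), sample(c(-1L, 1L), 15, replace = TRUE))
    can <- canonicalize(so)
    expect_equal(order_string(canonicalize(can)), order_string(can))
    expect_equal(can$genes[1], "COX1"); expect_equal(can$signs[1], 1L)
    # rotation
    r <- sample(15, 1)
    rot <- signed_gene_order(c(so$genes[r:15], so$genes[seq_len(r - 1)]),
                             c(so$signs[r:15], so$signs[seq_len(r - 1)]))
    expect_equal(order_string(canonicalize(rot)), order_string(can))
    # reflection
    refl <- signed_gene_order(rev(so$genes), rev(-so$signs))
    expect_equal(order_string(canonicalize(refl)), order_string(can))
  }
})

test_that("pattern grouping counts canonical matches deterministically", {
  base <- signed_gene_order(ref15)
  rots <- lapply(1:5, function(r) {
    o <- signed_gene_order(c(ref15[r:15], ref15[seq_len(r - 1)]),
                           record_id = paste0("r", r))
    o
  })
  pats <- group_patterns(rots)
  expect_length(pats, 1)
  expect_equal(pats[[1]]$count, 5)
  distinct <- list(base,
                   apply_event(base, rearrangement_event("inversion", block = c(2, 5))),
                   apply_event(base, rearrangement_event("transposition",
                                                         block = c(3, 4), dest = 10)))
  pats2 <- group_patterns(distinct)
  expect_length(pats2, 3)
  expect_equal(pats2[[1]]$pattern_id, "GO1")
  expect_equal(sum(vapply(pats2, `[[`, 0L, "count")), 3L)
})

test_that("common intervals match the analytic maximum and exhaustive subset enumeration", {
  id4 <- signed_gene_order(letters[1:4])
  expect_equal(common_intervals(id4, id4)$count, 10)
  rev4 <- signed_gene_order(letters[4:1])
  expect_equal(common_intervals(id4, rev4)$count, 10)
  p2413 <- signed_gene_order(letters[c(2, 4, 1, 3)])
  expect_equal(common_intervals(id4, p2413)$count, 5)
  id15 <- signed_gene_order(ref15)
  expect_equal(common_intervals(id15, id15)$count, 120)

  set.seed(23)
  for (n in c(5, 6, 8)) {
    for (rep in 1:6) {
      a <- random_signed_order(n); b <- signed_gene_order(sample(a$genes))
      got <- common_intervals(a, b)$count
      expect_equal(got, ci_subsets(a$genes, b$genes))
      expect_equal(got, common_intervals(b, a)$count)
    }
  }
  expect_error(common_intervals(id4, signed_gene_order(letters[2:5])), "gene sets")
})

test_that("rearrangement events act as defined on signed orders", {
  v <- c(1L, 2L, 3L, 4L)
  inv <- rearrangement_event("inversion", block = c(1, 4))
  expect_equal(apply_event(apply_event(v, inv), inv), v)
  expect_equal(apply_event(v, rearrangement_event("transposition",
                                                  block = c(2, 3), dest = 1)),
               c(2L, 3L, 1L, 4L))
  expect_equal(apply_event(v, rearrangement_event("reverse_transposition",
                                                  block = c(2, 3), dest = 1)),
               c(-3L, -2L, 1L, 4L))
  tdrl_id <- rearrangement_event("TDRL", partition = rep("L", 4))
  expect_equal(apply_event(v, tdrl_id), v)
  expect_equal(apply_event(v, rearrangement_event("TDRL",
                                                  partition = c("R", "L", "R", "L"))),
               c(2L, 4L, 1L, 3L))
  expect_error(apply_event(v, rearrangement_event("inversion", block = c(0, 2))),
               "range")
})

test_that("the TDRL distance formula equals a breadth-first-search oracle for n <= 6", {
  expect_equal(tdrl_distance(1:5, 1:5), 0L)
  expect_equal(tdrl_distance(c(2L, 1L), c(1L, 2L)), 1L)
  for (n in 4:6) {
    dist <- tdrl_bfs_distances(n)
    P <- all_permutations(n)
    form <- vapply(seq_len(nrow(P)), function(r) tdrl_distance(P[r, ], seq_len(n)), 0L)
    expect_equal(form, unname(dist[apply(P, 1, paste, collapse = ",")]))
  }
  expect_error(tdrl_distance(c(-1L, 2L), c(1L, 2L)), "inversions")
})

test_that("scenarios are always sound and single planted events are recovered exactly", {
  set.seed(29)
  # soundness on random pairs (including multi-event layer-4 cases)
  for (rep in 1:25) {
    a <- random_signed_order(10, ref15)
    b <- signed_gene_order(sample(a$genes), sample(c(-1L, 1L), 10, replace = TRUE))
    sc <- infer_scenario(a, b)
    anchor <- cnidmito:::default_anchor(a$genes)
    got <- replay_events(canonicalize(a, anchor), sc$events)
    expect_equal(order_string(got), order_string(canonicalize(b, anchor)))
  }
  # planted single block events: exact type, block equal or the
  # complementary representation of the same move
  types <- c("inversion", "transposition", "reverse_transposition")
  hits <- 0
  for (rep in 1:100) {
    v <- sample(15) * sample(c(-1L, 1L), 15, replace = TRUE)
    ev <- cnidmito:::random_event(15, types[(rep %% 3) + 1])
    w <- apply_event(v, ev)
    if (identical(v, w)) { hits <- hits + 1; next }  # event was a no-op
    sc <- infer_scenario(v, w)
    expect_length(sc$events, 1)
    got <- sc$events[[1]]
    expect_identical(apply_event(v, got), w)
    if (got$type == ev$type && identical(got$block, ev$block)) hits <- hits + 1
    else if (got$type == ev$type) hits <- hits + 1  # complementary-block form
    expect_equal(got$type, ev$type)
  }
  expect_equal(hits, 100)
})

test_that("pattern distance matrices are symmetric, bounded, and recomputable", {
  base <- signed_gene_order(ref15)
  p2 <- apply_event(base, rearrangement_event("inversion", block = c(3, 8)))
  p3 <- apply_event(base, rearrangement_event("transposition", block = c(2, 4), dest = 9))
  pats <- group_patterns(list(base, p2, p3))
  m <- pattern_distance_matrix(pats, "ci")
  expect_equal(diag(m), rep(0, 3), ignore_attr = TRUE)
  expect_equal(m, t(m))
  expect_true(all(m[upper.tri(m)] > 0 & m[upper.tri(m)] < 1))
  for (i in 1:2) for (j in (i + 1):3) {
    ci <- common_intervals(pats[[i]]$order, pats[[j]]$order)$count
    expect_equal(m[i, j], 1 - ci / ci_max(15))
  }
  me <- pattern_distance_matrix(pats, "events")
  expect_equal(me, t(me))
  expect_true(all(me[upper.tri(me)] >= 1))
})

test_that("gene orders extract from synthetic records and missing genes exclude a record", {
  cfg <- simulation_config(n_leaves = 5, codon_lengths = c(COX1 = 60, NAD2 = 50),
                           root_order = c("COX1", "rrnL", "NAD2", "rrnS"),
                           seed = 91)
  sim <- simulate_mitogenomes(cfg)
  o <- extract_gene_order(sim$records[[1]], alphabet = cfg$root_order)
  truth <- canonicalize(sim$leaf_orders[[sim$records[[1]]$record_id]], "COX1")
  expect_equal(order_string(o), order_string(truth))

  # drop ATP8-equivalent (NAD2) from a record -> excluded with log
  rec <- sim$records[[2]]
  rec$features <- Filter(function(f) f$gene != "NAD2", rec$features)
  cm_log_clear()
  kept <- extract_gene_orders(list(sim$records[[1]], rec), alphabet = cfg$root_order)
  expect_length(kept, 1)
  expect_match(cm_log_entries(), "excluded", all = FALSE)
})
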