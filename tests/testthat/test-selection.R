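test_that("NG86 handles identical pairs, single synonymous changes, and is symmetric", {
  s <- "TTTGCTAAA"
  r0 <- ng86_pairwise(s, s)
  expect_equal(r0$dN, 0); expect_equal(r0$dS, 0); expect_true(is.na(r0$omega))

  r1 <- ng86_pairwise("TTTGCTAAA", "TTCGCTAAA")  # TTT->TTC, Phe->Phe
  expect_equal(r1$Sd, 1); expect_equal(r1$Nd, 0)
  expect_equal(r1$N + r1$S, 9)

  set.seed(13)
  sense <- sense_codons("5")
  a <- paste(sample(sense, 20, replace = TRUE), collapse = "")
  b <- paste(sample(sense, 20, replace = TRUE), collapse = "")
  rab <- ng86_pairwise(a, b); rba <- ng86_pairwise(b, a)
  expect_equal(rab$dN, rba$dN); expect_equal(rab$dS, rba$dS)
  expect_error(ng86_pairwise("AAA", "AAAA"), "mismatch")
})

test_that("NG86 agrees with an independent pathway-enumeration oracle on random 50-codon pairs", {
  set.seed(101)
  sense <- sense_codons("5")
  for (rep in 1:4) {
    base <- sample(sense, 50, replace = TRUE)
    mut <- base
    idx <- sample(50, 12)
    mut[idx] <- sample(sense, 12, replace = TRUE)
    got <- ng86_pairwise(paste(base, collapse = ""), paste(mut, collapse = ""))
    want <- ng86_oracle(paste(base, collapse = ""), paste(mut, collapse = ""))
    expect_equal(got$N, want$N, tolerance = 1e-9)
    expect_equal(got$S, want$S, tolerance = 1e-9)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-9)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-9)
  }
})

sim_small <- function(n_leaves, L, seed, omega = c(omega = 0.2), fg = NULL,
                      depth = 0.3) {
  cfg <- simulation_config(n_leaves = n_leaves, codon_lengths = c(G1 = L),
                           root_order = c("G1", "rrnS", "rrnL"),
                           tree_depth = depth, omega = omega, foreground = fg,
                           seed = seed)
  tree <- simulate_tree(cfg)
  if (!is.null(fg)) cfg$foreground <- fg
  cs <- evolve_codon_sequences(tree, cfg)
  list(aln = cs$alignments$G1, tree = tree)
}

test_that("the pruning likelihood hits its limit cases and is column-permutation invariant", {
  # single codon, identical across taxa, near-zero branch lengths
  tree <- ape::read.tree(text = "((a:1e-9,b:1e-9):1e-9,(c:1e-9,d:1e-9):1e-9);")
  seqs <- setNames(rep("ATG", 4), c("a", "b", "c", "d"))
  aln <- codon_alignment(seqs, genetic_code_id = "5")
  bct <- branch_class_tree(tree, "one_ratio")
  fr <- uniform_codon_frequencies("5")
  ll <- gy94_loglik(aln, bct, kappa = 2, omega_by_class = c(omega = 0.3),
                    codon_frequencies = fr)
  expect_equal(ll, log(fr[["ATG"]]), tolerance = 1e-6)

  sm <- sim_small(4, 40, seed = 31)
  bct2 <- branch_class_tree(sm$tree, "one_ratio")
  ll_a <- gy94_loglik(sm$aln, bct2, 2, c(omega = 0.2))
  perm <- sm$aln
  perm$codons <- perm$codons[, sample(ncol(perm$codons))]
  ll_b <- gy94_loglik(perm, bct2, 2, c(omega = 0.2))
  expect_equal(ll_a, ll_b, tolerance = 1e-9)
})

test_that("pruning equals exhaustive internal-state summation on a 4-taxon, 30-codon case", {
  sm <- sim_small(4, 30, seed = 41)
  bct <- branch_class_tree(sm$tree, "one_ratio")
  freqs <- cnidmito:::prepare_freqs("f3x4", sm$aln)
  for (pars in list(c(2, 0.2), c(5, 1.2))) {
    ll_prune <- gy94_loglik(sm$aln, bct, pars[1], c(omega = pars[2]),
                            codon_frequencies = freqs)
    ll_sum <- gy94_exhaustive(sm$aln, sm$tree, pars[1], pars[2], freqs)
    expect_equal(ll_prune, ll_sum, tolerance = 1e-6)
  }
})

test_that("branch lengths sit at a local likelihood optimum after joint optimisation", {
  sm <- sim_small(4, 60, seed = 43)
  fit <- fit_branch_model(sm$aln, sm$tree, "one_ratio",
                          optimize_branch_lengths = TRUE)
  bct <- branch_class_tree(sm$tree, "one_ratio")
  freqs <- cnidmito:::prepare_freqs("f3x4", sm$aln)
  sp <- cnidmito:::site_patterns(sm$aln)
  ll_at <- function(bl) cnidmito:::gy94_loglik_prepared(
    sp, sm$aln, bct, fit$kappa, fit$omega, freqs, blens = bl)
  base <- ll_at(fit$blens)
  for (e in c(1, 3)) {
    for (fac in c(0.7, 1.4)) {
      bl <- fit$blens; bl[e] <- bl[e] * fac
      expect_lte(ll_at(bl), base + 1e-4)
    }
  }
})

test_that("model fits respect nesting and free-ratio returns one omega per unrooted branch", {
  sm <- sim_small(4, 50, seed = 47)
  f1 <- fit_branch_model(sm$aln, sm$tree, "one_ratio")
  fg <- ape::extract.clade(sm$tree, ape::Ntip(sm$tree) + 2)$tip.label
  f2 <- fit_branch_model(sm$aln, sm$tree, "two_ratio", foreground_set = fg,
                         null_fit = f1)
  expect_gte(f2$lnL, f1$lnL - 1e-6)
  ff <- fit_branch_model(sm$aln, sm$tree, "free_ratio", null_fit = f1)
  expect_length(ff$omega, 5)       # 4-taxon unrooted tree has 5 branches
  expect_gte(ff$lnL, f1$lnL - 1e-6)
  expect_true(all(ff$omega >= 0))
})

test_that("one-ratio estimates recover the simulating omega", {
  sm <- sim_small(6, 300, seed = 7)
  fit <- fit_branch_model(sm$aln, sm$tree, "one_ratio")
  expect_gte(fit$omega[[1]], 0.1)
  expect_lte(fit$omega[[1]], 0.35)
  expect_true(fit$convergence)
})

test_that("the LRT follows 2dlnL against chi-square with omega-count df", {
  mkfit <- function(lnL, k) structure(list(lnL = lnL, omega = setNames(
    rep(0.2, k), paste0("w", 1:k))), class = "codon_model_fit")
  eq <- lrt(mkfit(-100, 1), mkfit(-100, 2))
  expect_equal(eq$statistic, 0); expect_equal(eq$p, 1)
  near5 <- lrt(mkfit(-100, 1), mkfit(-100 + 3.84 / 2, 2))
  expect_equal(near5$p, 0.05, tolerance = 0.002)
  expect_equal(near5$df, 1)
  expect_error(lrt(mkfit(-100, 1), mkfit(-101, 2)), "nested")
})

test_that("clade omega comparisons mirror the rank test and flag strong separations", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,(e:1,f:1):1);")
  fit <- structure(list(
    model = "free_ratio", bct = list(tree = tree),
    classes = paste0("b", seq_len(nrow(tree$edge))),
    omega = setNames(c(0.1, 0.11, 0.12, 1.0, 1.1, 1.2, 0.5, 0.6, 0.7),
                     paste0("b", seq_len(nrow(tree$edge))))),
    class = "codon_model_fit")
  # clades of tips: edges inside clade {a,b} get the first branches, etc.
  clade_map <- list(AB = c("a", "b"), CD = c("c", "d"))
  out <- compare_clade_omegas(list(G = fit), clade_map)
  expect_equal(nrow(out), 1)
  expect_true(out$p <= 1 && out$p >= 0)
  expect_error(compare_clade_omegas(list(G = fit), list(AB = c("a", "zz"))),
               "absent")
})
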