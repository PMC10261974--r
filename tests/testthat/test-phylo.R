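test_that("sequence distances follow their model formulas", {
  a <- alignment(c(x = "ACGTACGTAC", y = "ACGTACGTAC"))
  for (m in c("p", "jc", "k2p"))
    expect_equal(unname(sequence_distance(a, m)["x", "y"]), 0)
  b <- alignment(c(x = "ACGTACGTAC", y = "ACGAACGTAT"))
  expect_equal(unname(sequence_distance(b, "p")["x", "y"]), 0.2)
  set.seed(19)
  s1 <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  s2chars <- strsplit(s1, "")[[1]]
  idx <- sample(200, 30)
  s2chars[idx] <- vapply(s2chars[idx], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  cc <- alignment(c(x = s1, y = paste(s2chars, collapse = "")))
  p <- unname(sequence_distance(cc, "p")["x", "y"])
  expect_equal(unname(sequence_distance(cc, "jc")["x", "y"]),
               -0.75 * log(1 - 4 * p / 3), tolerance = 1e-12)
})

test_that("neighbor joining recovers additive trees exactly, with non-negative branches", {
  # tree ((A:1,B:2):1,(C:3,D:1)); pairwise path lengths
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 3
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 4
  d["C", "D"] <- d["D", "C"] <- 4
  tr <- nj_tree(d)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[rownames(d), colnames(d)]),
               unname(d), tolerance = 1e-9)
  want <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1));")
  expect_equal(ape::dist.topo(ape::unroot(want), tr), structure(0, names = "PH85"),
               ignore_attr = TRUE)

  # random additive matrices round-trip the generating topology
  set.seed(33)
  for (n in c(5, 8, 10)) {
    gen <- ape::rtree(n)
    gen$edge.length <- gen$edge.length + 0.1
    m <- as.matrix(ape::cophenetic.phylo(gen))
    tr2 <- nj_tree(m)
    expect_equal(ape::dist.topo(ape::unroot(gen), tr2), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    expect_true(all(tr2$edge.length >= 0))
  }

  # degenerate all-equal distances still give a valid deterministic tree
  eq <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4])); diag(eq) <- 0
  t1 <- nj_tree(eq); t2 <- nj_tree(eq)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_setequal(t1$tip.label, letters[1:4])

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "square|>= 3")
  asym <- eq; asym[1, 2] <- 2
  expect_error(nj_tree(asym), "asymmetric")
})

test_that("bootstrap supports are 100 for unambiguous data, bounded, and seed-reproducible", {
  set.seed(3)
  # clear two-clade signal: identical columns within clades
  blockA <- paste(rep("A", 30), collapse = ""); blockC <- paste(rep("C", 30), collapse = "")
  aln <- alignment(c(a = paste0(blockA, blockA), b = paste0(blockA, blockA),
                     c = paste0(blockC, blockC), d = paste0(blockC, blockC),
                     e = paste0(blockA, blockC)))
  tr <- bootstrap_support(aln, B = 25, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  tr2 <- bootstrap_support(aln, B = 25, seed = 5)
  expect_equal(tr$node.label, tr2$node.label)

  uniform <- alignment(c(a = "AAAACCCCGGGG", b = "AAAACCCCGGGG",
                         c = "TTTTCCCCGGGG", d = "TTTTCCCAGGGG"))
  # identical columns across resamples keep the same splits every time
  tru <- bootstrap_support(uniform, B = 10, seed = 1)
  expect_true(all(suppressWarnings(as.numeric(tru$node.label)) %in% c(NA, 0, 100)))
})

test_that("monophyly is judged on the tree rooted at the outgroup", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(is_monophyletic(tr, c("A", "B"), "D"))
  expect_false(is_monophyletic(tr, c("A", "C"), "D"))
  expect_error(is_monophyletic(tr, c("A", "Z"), "D"), "Z")
  set.seed(37)
  for (i in 1:10) {
    gen <- ape::rtree(7)
    node <- sample((ape::Ntip(gen) + 2):(ape::Ntip(gen) + gen$Nnode), 1)
    clade <- ape::extract.clade(gen, node)$tip.label
    out <- setdiff(gen$tip.label, clade)[1]
    if (length(clade) >= 2 && length(clade) < 6)
      expect_true(is_monophyletic(gen, clade, out))
  }
})
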