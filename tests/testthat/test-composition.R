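test_that("base composition counts unambiguous bases and flags degenerate input", {
  bc <- base_composition("ATGC")
  expect_equal(bc$at_percent, 50)
  expect_equal(base_composition("AAAA")$at_percent, 100)
  nn <- base_composition("NNNN")
  expect_equal(nn$A + nn$C + nn$G + nn$T, 0L)
  expect_true(is.na(nn$at_percent))
  expect_true(is.na(nn$at_skew))
})

test_that("skews follow (A-T)/(A+T) and (G-C)/(G+C) with NA on empty denominators", {
  expect_equal(at_skew(list(A = 30, T = 30)), 0)
  expect_equal(at_skew(list(A = 3, T = 1)), 0.5)
  expect_true(is.na(gc_skew(list(G = 0, C = 0))))
  set.seed(1)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
    bc <- base_composition(s)
    expect_true(bc$at_skew >= -1 && bc$at_skew <= 1)
    expect_true(bc$gc_skew >= -1 && bc$gc_skew <= 1)
    gc_pct <- 100 * (bc$G + bc$C) / (bc$A + bc$C + bc$G + bc$T)
    expect_equal(bc$at_percent, 100 - gc_pct)
  }
})

test_that("RSCU matches its definition and family sums equal family sizes", {
  # Lys family AAA/AAG (2 codons) with counts 3 and 1
  r <- rscu(c("AAAAAAAAAAAG"), genetic_code_id = "5")
  expect_equal(unname(r$rscu["AAA"]), 1.5)
  expect_equal(unname(r$rscu["AAG"]), 0.5)
  # uniform 4-codon Val family
  r2 <- rscu("GTTGTCGTAGTG")
  expect_equal(unname(r2$rscu[c("GTT", "GTC", "GTA", "GTG")]), rep(1, 4))
  # unused families are NA
  expect_true(all(is.na(r$rscu[r$counts == 0 &
    !names(r$counts) %in% c("AAA", "AAG")][1])))
  expect_error(rscu("AAA", genetic_code_id = "99"), "supported")

  # property: family sums equal family size for every non-empty family
  set.seed(7)
  gc <- genetic_code("5")
  sense <- sense_codons("5")
  for (i in 1:10) {
    cds <- paste(sample(sense, 200, replace = TRUE), collapse = "")
    rr <- rscu(cds)
    aa <- gc[names(rr$rscu)]
    for (a in unique(aa)) {
      fam <- names(rr$rscu)[aa == a]
      if (sum(rr$counts[fam]) > 0)
        expect_equal(sum(rr$rscu[fam]), length(fam))
    }
  }
})

test_that("group summaries use sample SD and flag singletons; means match brute force", {
  tab <- data.frame(record_id = c("a", "b", "c"),
                    length = c(18000, 20000, 15000),
                    at_percent = c(60, 62, 70))
  tax <- data.frame(record_id = c("a", "b", "c"),
                    class = c("X", "X", "Y"))
  gs <- summarize_groups(tab, tax, "class")
  gx <- gs[gs$group == "X", ]
  expect_equal(gx$mean_length, 19000)
  expect_equal(gx$sd_length, sd(c(18000, 20000)), tolerance = 1e-9)
  expect_equal(round(gx$sd_length, 1), 1414.2)
  gy <- gs[gs$group == "Y", ]
  expect_true(gy$single_member)
  expect_equal(gy$sd_length, 0)

  set.seed(3)
  big <- data.frame(record_id = sprintf("r%02d", 1:30),
                    length = rnorm(30, 17000, 1000))
  btax <- data.frame(record_id = big$record_id,
                     class = rep(c("P", "Q", "R"), each = 10))
  gs2 <- summarize_groups(big, btax, "class")
  brute <- tapply(big$length, btax$class, mean)
  expect_equal(gs2$mean_length, as.numeric(brute[gs2$group]), tolerance = 1e-12)
})

test_that("two-group comparison is an exchangeable rank test with exact small-sample p", {
  expect_equal(compare_groups(list(a = c(1, 2, 3), b = c(1, 2, 3)), "a", "b")$p, 1)
  x <- c(1, 2, 3); y <- c(10, 11, 12)
  got <- compare_groups(list(a = x, b = y), "a", "b")
  expect_equal(got$method, "exact")
  expect_equal(got$p, wilcox_exact_oracle(x, y))
  expect_equal(got$p, compare_groups(list(a = x, b = y), "b", "a")$p)
  big <- compare_groups(list(a = 1:20, b = 101:120), "a", "b")
  expect_lt(big$p, 0.001)
  expect_error(compare_groups(list(a = 1:3, b = numeric(0)), "a", "b"), "empty")
})

test_that("skew correlation is Pearson's R over defined pairs", {
  tab <- data.frame(at_skew = seq(-0.2, 0.2, length.out = 10),
                    gc_skew = -seq(-0.2, 0.2, length.out = 10))
  expect_equal(skew_correlation(tab)$r, -1)
  set.seed(11)
  tab2 <- data.frame(at_skew = rnorm(20, 0, 0.05), gc_skew = rnorm(20, 0, 0.05))
  got <- skew_correlation(tab2)
  x <- tab2$at_skew; y <- tab2$gc_skew
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, manual, tolerance = 1e-12)
  expect_error(skew_correlation(data.frame(at_skew = 1:2, gc_skew = 2:1)), ">= 3")
})
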