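test_that("GenBank parsing reads records, topology, strands and wraps", {
  path <- write_genbank_fixture(tempfile(fileext = ".gb"))
  recs <- read_genbank(path)
  expect_length(recs, 2)
  expect_equal(recs[[1]]$record_id, "TEST1")
  expect_equal(recs[[1]]$topology, "circular")
  expect_equal(recs[[2]]$topology, "linear")
  expect_equal(recs[[1]]$taxon, "Testus firstus")

  cds <- recs[[1]]$features[[1]]
  expect_equal(cds$gene, "COX1")
  expect_equal(cds$strand, "-")
  expect_equal(cds$start, 9L)
  expect_equal(cds$end, 20L)
  expect_false(cds$wraps_origin)

  rrna <- recs[[1]]$features[[2]]
  expect_equal(rrna$gene, "rrnL")
  expect_true(rrna$wraps_origin)
  expect_equal(nchar(extract_gene_sequence(recs[[1]], rrna)), 11L)

  expect_equal(recs[[2]]$features[[1]]$gene, "NAD4L")
})

test_that("gene-name normalisation maps synonyms, leaves the rest as OTHER, idempotently", {
  expect_equal(normalize_gene_name("ND4L"), "NAD4L")
  expect_equal(normalize_gene_name("COI"), "COX1")
  expect_equal(normalize_gene_name("16S ribosomal RNA"), "rrnL")
  expect_equal(normalize_gene_name("12S"), "rrnS")
  expect_equal(normalize_gene_name("tRNA-Met"), "trnM")
  expect_equal(normalize_gene_name("mutS"), "OTHER")
  expect_equal(normalize_gene_name("ORF314"), "OTHER")
  for (raw in c("ND4L", "COI", "cob", "mutS", "rrnL", "ATPase 6")) {
    once <- normalize_gene_name(raw)
    expect_equal(normalize_gene_name(once), once)
  }
})

test_that("gene sequences are extracted strand- and wrap-aware", {
  rec <- mitogenome_record("r1", "ATGCCC", list(
    gene_feature("g+", gene = "OTHER", kind = "other", strand = "+", start = 0, end = 3),
    gene_feature("g-", gene = "OTHER", kind = "other", strand = "-", start = 0, end = 3)))
  expect_equal(extract_gene_sequence(rec, rec$features[[1]]), "ATG")
  expect_equal(extract_gene_sequence(rec, rec$features[[2]]), "CAT")

  wrec <- mitogenome_record("r2", "AAAATG", list(
    gene_feature("w", gene = "OTHER", kind = "other", strand = "+",
                 start = 4, end = 2, wraps_origin = TRUE)), topology = "circular")
  expect_equal(extract_gene_sequence(wrec, wrec$features[[1]]), "TGAA")

  expect_error(
    mitogenome_record("r3", "AAAATG", list(
      gene_feature("w", gene = "OTHER", kind = "other", strand = "+",
                   start = 4, end = 2, wraps_origin = TRUE)), topology = "linear"),
    "linear")
})

test_that("feature tables and newick round-trip; malformed TSV rows name their line", {
  recs <- list(
    mitogenome_record("A1", paste(rep("ACGT", 30), collapse = ""), list(
      gene_feature("COX1", strand = "+", start = 0, end = 30),
      gene_feature("rrnS", strand = "-", start = 40, end = 80))),
    mitogenome_record("B2", paste(rep("TTGC", 25), collapse = ""), list(
      gene_feature("NAD5", strand = "+", start = 10, end = 70))))
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  ss <- Biostrings::DNAStringSet(vapply(recs, `[[`, "", "sequence"))
  names(ss) <- vapply(recs, `[[`, "", "record_id")
  Biostrings::writeXStringSet(ss, fa)
  write_feature_table(recs, tsv)
  back <- read_feature_table(fa, tsv)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_equal(back[[i]]$sequence, recs[[i]]$sequence)
    expect_equal(lapply(back[[i]]$features, `[`, c("gene", "strand", "start", "end")),
                 lapply(recs[[i]]$features, `[`, c("gene", "strand", "start", "end")))
  }

  nwk <- tempfile(fileext = ".nwk")
  tr <- ape::read.tree(text = "(A:1,(B:1,C:1):1);")
  write_newick(tr, nwk)
  tr2 <- read_newick(nwk)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), structure(0, names = "PH85"),
               ignore_attr = TRUE)
  expect_equal(sort(tr2$edge.length), sort(tr$edge.length))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb\tc\td\te", "1\t2\t3\t4\t5", "1\t2\t3"), bad)
  expect_error(read_tsv_strict(bad), "line 3")
})

test_that("duplicate canonical symbols keep the first by start coordinate", {
  rec <- mitogenome_record("d1", paste(rep("ACGT", 30), collapse = ""), list(
    gene_feature("COX1", strand = "+", start = 50, end = 70),
    gene_feature("CO1", gene = "COX1", strand = "+", start = 5, end = 25)))
  cm_log_clear()
  dd <- dedupe_features(rec)
  expect_length(dd$features, 1)
  expect_equal(dd$features[[1]]$start, 5L)
  expect_match(cm_log_entries(), "duplicate", all = FALSE)
})
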