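test_that("FASTA, relaxed PHYLIP and NEXUS round-trip sequence content", {
  recs <- setNames(c("ACGTACGTAC", "ACGTACGTAG", "ACGTATGTAG"),
                   c("a1", "a2", "a3"))
  tmp <- tempfile()
  write_records(recs, tmp, "fasta")
  expect_identical(unname(read_records(tmp, "fasta")), unname(recs))

  write_records(recs, tmp, "phylip_relaxed")
  expect_identical(readLines(tmp)[1], "3 10")
  expect_identical(read_records(tmp, "phylip_relaxed")$seqs, unname(recs))

  write_records(ribo_alignment(names(recs), recs), tmp, "nexus")
  expect_identical(read_records(tmp, "nexus")$seqs, unname(recs))

  # simulator family of 20+: identical residues per id after a round trip
  sim <- simulate_family(sim_config(), seed = 4)
  write_records(sim$alignment, tmp, "fasta")
  back <- read_records(tmp, "fasta", aligned = TRUE)
  expect_identical(back$seqs[match(sim$alignment$ids, back$ids)],
                   sim$alignment$seqs)
})

test_that("readers reject malformed input and duplicates", {
  tmp <- tempfile()
  writeLines(character(0), tmp)
  expect_error(read_records(tmp, "fasta"), "no records")
  writeLines(c(">x", "ACGT", ">x", "ACGA"), tmp)
  expect_error(read_records(tmp, "fasta"), "duplicate")
  writeLines(c("2 4", "a ACGT", "b ACG"), tmp)
  expect_error(read_records(tmp, "phylip_relaxed"), "row length")
  expect_error(write_records(c(a = "ACGT", b = "ACG"), tmp, "phylip_relaxed"),
               "ragged")
})

test_that("NEXUS with an indel partition declares both charsets", {
  m <- rbind(a1 = .s2v_test("AC--GT"), a2 = .s2v_test("ACGTGT"),
             a3 = .s2v_test("AC--GT"))
  sic <- sic_code(m)
  aln <- ribo_alignment(rownames(m), apply(m, 1, paste, collapse = ""))
  tmp <- tempfile()
  write_records(aln, tmp, "nexus", indels = sic)
  txt <- readLines(tmp)
  expect_true(any(grepl("CHARSET dna", txt)))
  expect_true(any(grepl("CHARSET indels", txt)))
  expect_true(any(grepl("RESTRICTION", txt)))
  # gap stripping flag for unaligned export
  write_records(aln, tmp, "fasta", strip_gaps = TRUE)
  expect_false(any(grepl("-", readLines(tmp), fixed = TRUE)))
})

test_that("Newick round-trip preserves splits, lengths and supports", {
  tmp <- tempfile()
  tr <- ape::read.tree(text = "((A:0.1,B:0.2)0.98:0.05,C:0.3);")
  write_newick(tr, tmp)
  back <- read_newick(tmp)
  expect_identical(back$node.label[2], "0.98")
  set.seed(1)
  tr50 <- ape::rtree(50)
  write_newick(tr50, tmp)
  back <- read_newick(tmp)
  expect_identical(split_keys(back), split_keys(tr50))
  s1 <- ribosort:::.tree_splits(tr50); s2 <- ribosort:::.tree_splits(back)
  expect_equal(s2$internal[names(s1$internal)], s1$internal, tolerance = 1e-9)
  expect_error(read_newick({ writeLines("((A,B,C);", tmp); tmp }))
})

test_that("region annotation recovers constructed boundaries and shifts with prefix length", {
  set.seed(2)
  its1 <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  its2 <- paste(sample(c("A", "C", "G", "T"), 220, TRUE), collapse = "")
  s <- paste0(its1, ribosort:::.REF_5_8S, its2)
  ann <- annotate_regions(s)
  expect_true(ann$anchored)
  expect_equal(ann$its1, c(0, 200))
  expect_equal(ann$r5_8s, c(200, 360))
  expect_equal(ann$its2, c(360, nchar(s)))
  # translation equivariance: prepending k residues shifts every boundary by
  # k except the ITS1 start, which is the sequence start by definition
  k <- 17
  ann2 <- annotate_regions(paste0(strrep("A", k), s))
  expect_equal(ann2$r5_8s, ann$r5_8s + k)
  expect_equal(ann2$its2, ann$its2 + k)
  expect_equal(ann2$its1[2], ann$its1[2] + k)

  # no anchor within the mismatch budget -> proportional fallback, flagged
  s_no <- gsub("GAATTGCAGAATCC", "TTTTTTTTTTTTTT", s, fixed = TRUE)
  ann3 <- annotate_regions(s_no)
  expect_false(ann3$anchored)
  # anchor at position 0 would leave an empty ITS1 -> flagged
  s0 <- paste0(ribosort:::.REF_5_8S, its2, its1)
  expect_false(annotate_regions(s0)$anchored)
  expect_error(annotate_regions("ACGT"), "shorter")
})
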