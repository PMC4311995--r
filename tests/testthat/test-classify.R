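test_that("gc_content counts only unambiguous bases", {
  expect_equal(gc_content("GCGC", c(0, 4)), 1.0)
  expect_equal(gc_content("ATAT", c(0, 4)), 0.0)
  expect_equal(gc_content("GA-TC", c(0, 5)), 0.5)
  expect_error(gc_content("NN--N", c(0, 5)), "countable")
})

test_that("motif_scan finds the leftmost best window and respects the budget", {
  motif <- "GAATTGCAGAATCC"
  s <- paste0("ACGTACGT", motif, "TTTT")
  hit <- motif_scan(s, motif, max_mismatch = 0)
  expect_true(hit$present)
  expect_equal(hit$best_pos, 8)
  expect_equal(hit$mismatches, 0)
  expect_true(motif_scan(motif, motif, 0)$present)
  expect_equal(motif_scan(motif, motif, 0)$best_pos, 0)
  # three substitutions, budget 1 -> absent
  broken <- paste0("ACGTACGT", "GTTTTGCAGAAACC", "TTTT")
  expect_false(motif_scan(broken, motif, max_mismatch = 1)$present)
  # gap columns removed before scanning
  gapped <- paste0("AC--GT", substr(motif, 1, 7), "--", substr(motif, 8, 14))
  expect_true(motif_scan(gapped, motif, 0)$present)
  expect_null(motif_scan("ACGT", motif, 1)$best_pos)
})

test_that("fold_mfe equals the enumeration oracle and behaves monotonically", {
  expect_equal(fold_mfe("AAAAAAAAAA"), 0)
  set.seed(31)
  for (r in 1:12) {
    v <- sample(c("A", "C", "G", "T"), sample(10:13, 1), replace = TRUE)
    expect_equal(fold_mfe(paste(v, collapse = "")), enum_fold(v),
                 tolerance = 1e-12)
  }
  expect_equal(fold_mfe("GGGGAAAACCCC"),
               enum_fold(.s2v_test("GGGGAAAACCCC")))
  # a sequence plus its duplicate (4-A linker) can only fold as well or better
  s <- "GGCAUAGCUUAGCC"
  s <- gsub("U", "T", s)
  dup <- paste0(s, "AAAA", s)
  expect_lte(fold_mfe(dup), fold_mfe(s))
  expect_error(fold_mfe("ANNNNNACGTNNN"), "ambiguous")
  expect_error(fold_mfe("ACG-TACGTACG"), "gap-free")
})

test_that("relative_rate matches its definition and guards division by zero", {
  base <- strrep("A", 300)
  mut <- function(s, idx) {
    v <- .s2v_test(s); v[idx] <- "C"; paste(v, collapse = "")
  }
  # refs differ pairwise at exactly 20 sites; the focal's 30 private changes
  # plus each ref's 10 private changes give d(f, ref) = 40
  r1 <- mut(base, 1:10)          # d(r1, r2) = 20
  r2 <- mut(base, 11:20)
  f <- mut(base, 271:300)
  aln <- ribo_alignment(c("f", "r1", "r2"), c(f, r1, r2))
  expect_equal(relative_rate(aln, "f", c("r1", "r2")),
               (40 / 300) / (20 / 300))
  # focal equal to one reference: mean distance (0 + 20)/2 = 10
  aln2 <- ribo_alignment(c("f", "r1", "r2"), c(r1, r1, r2))
  expect_equal(relative_rate(aln2, "f", c("r1", "r2")), 10 / 20)
  aln3 <- ribo_alignment(c("f", "r1", "r2"), c(base, base, base))
  expect_equal(relative_rate(aln3, "f", c("r1", "r2")), 0)
  # identical references, divergent focal -> +Inf with a warning
  aln4 <- ribo_alignment(c("f", "r1", "r2"), c(f, base, base))
  expect_warning(rr <- relative_rate(aln4, "f", c("r1", "r2")), "identical")
  expect_identical(rr, Inf)
  # star geometry: focal on a branch m-times longer than each reference's;
  # expected ratio (m + 1)/2 in expectation (p-distances, low divergence)
  set.seed(8)
  m <- 5
  tr <- ape::read.tree(text = sprintf(
    "(f:%f,r1:0.02,r2:0.02,r3:0.02,r4:0.02);", 0.02 * m))
  ratios <- replicate(20, {
    mm <- sim_seqs(tr, 2000)
    relative_rate(ribo_alignment(rownames(mm),
                                 apply(mm, 1, paste, collapse = "")),
                  "f", paste0("r", 1:4))
  })
  # saturation-corrected oracle: expected p-distances under JC
  pdist <- function(d) 0.75 * (1 - exp(-4 * d / 3))
  expected <- pdist(0.02 * m + 0.02) / pdist(2 * 0.02)
  expect_equal(mean(ratios), expected, tolerance = 0.1)
})

test_that("classify_paralogs separates simulated pseudogenes from functionals", {
  sim <- simulate_family(sim_config(n_recombinants = 0), seed = 21)
  calls <- classify_paralogs(sim$alignment)
  truth <- sim$truth$labels
  acc <- mean(calls$label[match(truth$id, calls$id)] == truth$class)
  expect_gte(acc, 0.95)
})

test_that("classification is order-invariant and monotone in the GC cutoff", {
  sim <- simulate_family(sim_config(n_recombinants = 0), seed = 22)
  aln <- sim$alignment
  calls <- classify_paralogs(aln)
  set.seed(1)
  perm <- sample(length(aln$ids))
  aln_p <- ribo_alignment(aln$ids[perm], aln$seqs[perm])
  calls_p <- classify_paralogs(aln_p)
  expect_identical(calls$label[match(aln$ids, calls$id)],
                   calls_p$label[match(aln$ids, calls_p$id)])
  # lowering gc_z_cut can only grow the pseudogene set
  loose <- classify_paralogs(aln, classify_thresholds(gc_z_cut = 0.5))
  strict_set <- calls$id[calls$label == "pseudogene"]
  loose_set <- loose$id[loose$label == "pseudogene"]
  expect_true(all(strict_set %in% loose_set))
})

test_that("degenerate classification inputs are handled", {
  # all identical, motif-bearing -> all functional with zero votes
  s <- paste0(strrep("ACGT", 60), ribosort:::.REF_5_8S, strrep("GTCA", 60))
  aln <- ribo_alignment(paste0("c", 1:5), rep(s, 5))
  calls <- classify_paralogs(aln)
  expect_true(all(calls$label == "functional"))
  expect_true(all(calls$votes == 0))
  # provisional pool too small -> informative error
  no_motif <- gsub("GAATTGCAGAATCC", "TTTTTTTTTTTTTT", s, fixed = TRUE)
  aln2 <- ribo_alignment(paste0("c", 1:5), c(s, rep(no_motif, 4)))
  expect_error(classify_paralogs(aln2), "functional baseline")
})
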