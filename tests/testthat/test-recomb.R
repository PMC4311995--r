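test_that("polymorphic_sites equals a per-column brute scan", {
  m <- rbind(a = .s2v_test("AAAA"), b = .s2v_test("AAAA"), c = .s2v_test("AAAA"))
  expect_identical(polymorphic_sites(m), integer(0))
  m[3, 2] <- "G"
  expect_identical(polymorphic_sites(m), 1L)
  set.seed(5)
  m2 <- matrix(sample(c("A", "C", "G", "T", "-", "N"), 5 * 100, TRUE,
                      prob = c(.23, .23, .23, .23, .05, .03)), 5, 100,
               dimnames = list(paste0("s", 1:5), NULL))
  brute <- which(vapply(seq_len(100), function(j) {
    u <- unique(m2[, j]); u <- u[u %in% c("A", "C", "G", "T")]
    length(u) >= 2
  }, TRUE)) - 1L
  expect_identical(polymorphic_sites(m2), brute)
})

test_that("best_fragment is exact, symmetric and correctly tie-broken", {
  # identical strings: whole range
  r <- best_fragment(strrep("A", 30), strrep("A", 30))
  expect_equal(r$score, 30)
  expect_equal(c(r$start, r$end), c(0, 30))
  # alternating match/mismatch with a crushing penalty: single best site,
  # leftmost
  mv <- rep(c(1L, 0L), 15)
  r2 <- best_fragment(mv, g = 100)
  expect_equal(r2$score, 1)
  expect_equal(c(r2$start, r2$end), c(0, 1))
  expect_identical(best_fragment(integer(0))$score, 0)
  # equality with the exhaustive all-intervals oracle
  set.seed(13)
  for (rep in 1:30) {
    mv <- rbinom(sample(5:200, 1), 1, runif(1, 0.2, 0.95))
    g <- sample(c(0.5, 1, 2), 1)
    expect_equal(best_fragment(mv, g = g)$score, brute_fragment(mv, g),
                 tolerance = 1e-9)
  }
  # symmetry in the pair
  a <- paste(sample(c("A", "C"), 50, TRUE), collapse = "")
  b <- paste(sample(c("A", "C"), 50, TRUE), collapse = "")
  expect_equal(best_fragment(a, b), best_fragment(b, a))
})

test_that("constructed chimera fragment covers the planted region", {
  set.seed(3)
  n <- 120
  a <- sample(c("A", "C", "G", "T"), n, TRUE)
  b <- a
  flip <- which(runif(n) < 0.3); flip <- flip[flip > 40]
  for (i in flip) b[i] <- sample(setdiff(c("A", "C", "G", "T"), a[i]), 1)
  bf <- best_fragment(paste(a, collapse = ""), paste(b, collapse = ""), g = 1)
  expect_lte(bf$start, 0)
  expect_gte(bf$end, 40)
  expect_equal(bf$score,
               brute_fragment(as.integer(a == b), 1), tolerance = 1e-9)
})

test_that("permutation p-values are valid and powered", {
  # observed score 0 -> p = 1
  aln0 <- ribo_alignment(c("x", "y"), c("AAAA", "CCCC"))
  expect_equal(permutation_pvalue(aln0, c("x", "y"),
                                  settings = recomb_settings(n_perm = 99)), 1.0)
  # planted 50-site identical tract in a 20%-divergent pair -> small p
  set.seed(9)
  pair <- simulate_null_pair(0.2, 500, seed = 41)
  m <- as.matrix(pair)
  m[2, 101:150] <- m[1, 101:150]
  p <- permutation_pvalue(m, c("s1", "s2"),
                          settings = recomb_settings(n_perm = 999, seed = 7))
  expect_lte(p, 0.01)
})

test_that("detect_recombinants flags planted chimeras and only them", {
  # no polymorphic sites -> nothing to test
  aln_c <- ribo_alignment(c("a", "b", "c"), rep("ACGTACGTAC", 3))
  det0 <- detect_recombinants(aln_c, recomb_settings(n_perm = 99))
  expect_equal(nrow(det0$hits), 0)
  expect_identical(det0$recombinants, character(0))
  hits_all <- 0; fp <- 0
  for (sd in c(31, 32, 33)) {
    sim <- simulate_family(sim_config(breakpoint = c(100, 130)), seed = sd)
    det <- suppressWarnings(detect_recombinants(
      sim$alignment, recomb_settings(n_perm = 7999, seed = 2)))
    tr <- sim$truth$recombinants$id
    hits_all <- hits_all + all(tr %in% det$recombinants)
    fp <- fp + length(setdiff(det$recombinants, tr))
  }
  expect_gte(hits_all, 2)
  expect_lte(fp, 1)
})

test_that("small n_perm triggers the Bonferroni attainability warning", {
  sim <- simulate_family(sim_config(n_species = 4, n_recombinants = 0),
                         seed = 2)
  expect_warning(detect_recombinants(sim$alignment,
                                     recomb_settings(n_perm = 99)),
                 "n_perm too small")
})
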