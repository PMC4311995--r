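test_that("the simulator is deterministic and validates its configuration", {
  s1 <- simulate_family(sim_config(), seed = 3)
  s2 <- simulate_family(sim_config(), seed = 3)
  expect_identical(s1$alignment$seqs, s2$alignment$seqs)
  expect_identical(s1$truth$labels, s2$truth$labels)
  expect_error(simulate_family(sim_config(n_species = 2, n_functional = 1,
                                          n_pseudogene = 0,
                                          n_recombinants = 1), seed = 1),
               "infeasible")
})

test_that("pseudogene effects show in GC, motif loss and rate", {
  gc_f <- c(); gc_p <- c(); knocked <- 0; n_pseudo <- 0
  for (sd in 1:10) {
    sim <- simulate_family(sim_config(n_recombinants = 0), seed = sd)
    aln <- annotate_alignment(sim$alignment)
    fx <- paralog_features(aln)
    lab <- sim$truth$labels$class[match(fx$id, sim$truth$labels$id)]
    gc_f <- c(gc_f, fx$gc_5_8s[lab == "functional"])
    gc_p <- c(gc_p, fx$gc_5_8s[lab == "pseudogene"])
    # every functional copy keeps the motif
    expect_true(all(fx$motif_present[lab == "functional"]))
    knocked <- knocked + sum(sim$truth$labels$motif_knocked)
    n_pseudo <- n_pseudo + sum(lab == "pseudogene")
  }
  expect_lt(mean(gc_p), mean(gc_f))
  # knockout fraction within the binomial 99% CI around 0.9
  ci <- qbinom(c(0.005, 0.995), n_pseudo, 0.9)
  expect_gte(knocked, ci[1])
  expect_lte(knocked, ci[2])
})

test_that("null pairs hit their nominal divergence", {
  p <- simulate_null_pair(0.2, 500, seed = 11)
  m <- as.matrix(p)
  d <- mean(m[1, ] != m[2, ])
  ci <- qbinom(c(0.005, 0.995), 500, 0.2) / 500
  expect_gte(d, ci[1]); expect_lte(d, ci[2])
  expect_identical(as.matrix(simulate_null_pair(0.2, 500, seed = 11)), m)
  p0 <- simulate_null_pair(1e-9, 100, seed = 1)
  expect_error(simulate_null_pair(0.8, 100), "divergence")
})

test_that("truth trees are reciprocally monophyletic with recoverable roots", {
  sim <- simulate_family(sim_config(), seed = 9)
  tt <- sim$truth$tree
  expect_true(check_reciprocal_monophyly(tt, sim$truth$functional,
                                         sim$truth$pseudogenes))
  rooted <- root_on_clade(ape::unroot(tt), sim$truth$pseudogenes)
  expect_true(ape::is.rooted(rooted))
  # recombinants are spliced rows, not tree tips
  expect_false(any(sim$truth$recombinants$id %in% tt$tip.label))
  expect_true(all(sim$truth$recombinants$breakpoint > 0 &
                  sim$truth$recombinants$breakpoint < sim$alignment$length))
  # area coding covers every species
  expect_setequal(sim$truth$areas$taxon, sim$truth$species_tree$tip.label)
})
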