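test_that("code_areas validates letters, taxa and multi-area rows", {
  df <- data.frame(taxon = c("t1", "t2"), areas = c("A", "BC"))
  am <- code_areas(df)
  expect_true(am["t1", "A"]) ; expect_false(am["t1", "B"])
  expect_true(all(am["t2", c("B", "C")]))
  expect_error(code_areas(data.frame(taxon = "x", areas = "D")), "unknown area")
  expect_error(code_areas(df, taxa = c("t1", "t2", "t3")), "missing taxa")
  tmp <- tempfile()
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(unclass(code_areas(tmp)), unclass(am))
})

test_that("a zero-length branch pins the parent node to the tip's area", {
  tr <- ape::read.tree(
    text = "((t1:0.0000001,t2:0.3):0.2,(t3:0.3,t4:0.3):0.2);")
  am <- code_areas(data.frame(taxon = paste0("t", 1:4),
                              areas = c("A", "B", "C", "BC")))
  post <- bbm_ancestral(tr, am, bbm_settings(n_generations = 20000,
    sample_every = 100, burnin_samples = 50, n_chains = 2, seed = 3))
  nd <- post$nodes[["t1|t2"]]
  expect_gte(nd$probs[["A"]], 0.99)
  # probabilities per node are a distribution over non-empty subsets
  for (x in post$nodes) expect_lte(sum(x$probs), 1 + 1e-9)
  expect_equal(nd$coverage, 1)
})

test_that("range summaries are consistent with the posteriors", {
  tr <- ape::rcoal(5)
  sa <- simulate_areas(tr, seed = 2)
  post <- bbm_ancestral(tr, code_areas(sa$areas),
                        bbm_settings(n_generations = 10000, sample_every = 100,
                                     burnin_samples = 20, n_chains = 2,
                                     seed = 5))
  tab <- summarize_ranges(post)
  expect_true(all(tab$best_prob > 0 & tab$best_prob <= 1))
  for (i in seq_len(nrow(tab)))
    expect_identical(tab$best_range[i],
                     names(post$nodes[[tab$node[i]]]$probs)[1])
})

test_that("simulate_areas is seeded and matches its tip-frequency expectations", {
  tr <- ape::rcoal(30)
  s1 <- simulate_areas(tr, seed = 4)
  s2 <- simulate_areas(tr, seed = 4)
  expect_identical(s1$areas, s2$areas)
  expect_true(all(nchar(s1$areas$areas) >= 1))
  expect_equal(nrow(s1$node_states), tr$Nnode)
})

test_that("max_areas redistribution leaves the three-area default untouched", {
  tr <- ape::rcoal(4)
  sa <- simulate_areas(tr, seed = 7)
  st <- bbm_settings(n_generations = 5000, sample_every = 100,
                     burnin_samples = 10, n_chains = 1, seed = 1)
  p3 <- bbm_ancestral(tr, code_areas(sa$areas), st)
  # |areas| = 3 and max_areas = 3: every reported subset has size <= 3
  for (x in p3$nodes)
    expect_true(all(nchar(names(x$probs)) <= 3))
  st2 <- st; st2$max_areas <- 1L
  p1 <- bbm_ancestral(tr, code_areas(sa$areas), st2)
  for (x in p1$nodes) {
    expect_true(all(nchar(names(x$probs)) <= 1))
    expect_lte(sum(x$probs), 1 + 1e-9)
  }
})
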