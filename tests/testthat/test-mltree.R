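test_that("AIC model choice respects nesting and recovers the generating model", {
  set.seed(19)
  tr <- ape::unroot(ape::rtree(6))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  # JC data: JC close to the best by AIC on most datasets (a richer nested
  # model can win by up to ~chi-square noise on any one dataset); GTR lnL
  # never below JC lnL
  gaps <- vapply(1:4, function(sd) {
    set.seed(sd)
    m <- sim_seqs(tr, 800, subst_model("JC69", gamma = FALSE))
    sel <- model_select_aic(m)
    tab <- sel$table
    expect_gte(tab$lnL[tab$kind == "GTR" & !tab$gamma],
               tab$lnL[tab$kind == "JC69" & !tab$gamma] - 1e-3)
    tab$AIC[tab$kind == "JC69" & !tab$gamma] - min(tab$AIC)
  }, 1)
  expect_gte(sum(gaps <= 2), 2)
  expect_lte(mean(gaps), 3)
  expect_true(all(gaps <= 7))
  # strongly non-JC data with rate heterogeneity: GTR + gamma wins
  set.seed(4)
  gen <- subst_model("GTR", rates = c(2, 6, 1.2, 1.5, 5, 1),
                     freqs = c(.35, .15, .3, .2), gamma = TRUE, alpha = 0.3)
  mG <- sim_seqs(tr, 2000, gen)
  selG <- model_select_aic(mG)
  expect_identical(selG$best$kind, "GTR")
  expect_true(selG$best$gamma)
})

test_that("ml_search recovers a long-internal-branch quartet and is order-invariant", {
  tru <- ape::read.tree(text = "((A:0.05,B:0.05):0.2,(C:0.05,D:0.05):0.2);")
  jc <- subst_model("JC69", gamma = FALSE)
  hits <- 0
  for (sd in 1:20) {
    set.seed(sd)
    m <- sim_seqs(ape::unroot(tru), 400, jc)
    fit <- ml_search(m, jc)
    hits <- hits + check_reciprocal_monophyly(fit$tree, c("A", "B"),
                                              c("C", "D"))
  }
  expect_gte(hits, 19)
  set.seed(77)
  m <- sim_seqs(ape::unroot(tru), 400, jc)
  f1 <- ml_search(m, jc)
  f2 <- ml_search(m[c(3, 1, 4, 2), ], jc)
  expect_identical(split_keys(f1$tree), split_keys(f2$tree))
  expect_equal(f1$lnL, f2$lnL, tolerance = 1e-6)
  expect_error(ml_search(m[1:3, ], jc), "at least 4")
})

test_that("bootstrap gives full support to a clean split and warns at zero reps", {
  set.seed(23)
  tru <- ape::read.tree(text = "((A:0.02,B:0.02):0.4,(C:0.02,D:0.02):0.4);")
  jc <- subst_model("JC69", gamma = FALSE)
  m <- sim_seqs(ape::unroot(tru), 300, jc)
  bs <- bootstrap_support(m, jc, n_reps = 50, seed = 3)
  expect_equal(bs$support$mlbs, 100)
  expect_warning(b0 <- bootstrap_support(m, jc, n_reps = 0), "n_reps")
  expect_null(b0$support)
})

test_that("the combined DNA+indel likelihood drives the search", {
  sim <- simulate_family(sim_config(n_species = 5, n_recombinants = 0),
                         seed = 12)
  m <- as.matrix(sim$alignment)
  sic <- sic_code(m)
  fit <- ml_search(m, subst_model("GTR", gamma = TRUE, alpha = 0.5),
                   sic = sic, bin_model = binary_model())
  expect_true(is.finite(fit$lnL))
  expect_identical(sort(fit$tree$tip.label), sort(rownames(m)))
})
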