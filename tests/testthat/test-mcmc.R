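jc <- subst_model("JC69", gamma = FALSE)

test_that("duplicate seeds give identical samples; settings are validated", {
  set.seed(51)
  m <- sim_seqs(ape::unroot(ape::rtree(5)), 100, jc)
  st <- mcmc_settings(n_generations = 500, sample_every = 10, n_chains = 2,
                      seed = 6)
  r1 <- mcmc_run(m, jc, settings = st, n_runs = 1)[[1]]
  r2 <- mcmc_run(m, jc, settings = st, n_runs = 1)[[1]]
  expect_identical(r1$lnL, r2$lnL)
  expect_identical(lapply(r1$trees, ape::write.tree),
                   lapply(r2$trees, ape::write.tree))
  # a single chain runs as plain Metropolis-Hastings (no swap machinery)
  st1 <- mcmc_settings(n_generations = 200, sample_every = 10, n_chains = 1)
  expect_s3_class(mcmc_run(m, jc, settings = st1, n_runs = 1)[[1]],
                  "tree_sample")
  expect_error(mcmc_settings(n_generations = 1001, sample_every = 10),
               "divisible|%%")
})

test_that("ASDSF is zero against itself and matches hand computation", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  mk <- function(trees) structure(list(gen = seq_along(trees), trees = trees,
                                       lnL = numeric(length(trees)),
                                       run_id = 1), class = "tree_sample")
  rA <- mk(rep(list(t1), 20))
  rB <- mk(rep(list(t2), 20))
  expect_equal(asdsf(rA, rA, burnin_frac = 0.25), 0)
  # two splits, each with frequencies (1, 0) across the runs:
  # sd(c(1, 0)) = 1/sqrt(2); mean over the two splits is the same
  expect_equal(asdsf(rA, rB, burnin_frac = 0), sd(c(1, 0)))
})

test_that("majority consensus keeps strict >50% splits with exact frequencies", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  mk <- function(trees) structure(list(gen = seq_along(trees), trees = trees,
                                       lnL = numeric(length(trees)),
                                       run_id = 1), class = "tree_sample")
  same <- majority_consensus(mk(rep(list(t1), 10)), burnin_frac = 0)
  expect_identical(split_keys(same), split_keys(t1))
  expect_true(all(same$node.label[nzchar(same$node.label)] == "1.0000"))
  mix <- majority_consensus(mk(c(rep(list(t1), 6), rep(list(t2), 4))),
                            burnin_frac = 0)
  expect_identical(split_keys(mix), split_keys(t1))
  expect_true("0.6000" %in% mix$node.label)
  # burn-in removes exactly the first 25%: 100 samples -> 75 used
  burn <- majority_consensus(mk(c(rep(list(t2), 25), rep(list(t1), 75))),
                             burnin_frac = 0.25)
  fr <- attr(burn, "split_freqs")
  expect_equal(unname(fr[split_keys(t1)]), 1.0)
  # mean branch length over trees containing the split (unrooted: the two
  # root-adjacent halves merge)
  expect_equal(ribosort:::.tree_splits(mix)$internal[[split_keys(t1)]], 2)
})

test_that("two-taxon branch-length posterior matches numeric integration", {
  n <- 200; k <- 30
  m <- rbind(A = rep("A", n), B = c(rep("C", k), rep("A", n - k)))
  logL <- function(s) {
    q <- 0.25 + 0.75 * exp(-4 * s / 3)
    (n - k) * log(0.25 * q) + k * log(0.25 * (1 - q) / 3)
  }
  # prior: the two pendant branches are iid Exp(10), so the identifiable
  # path length s is Gamma(2, 10)
  post_un <- function(s) exp(logL(s) + dgamma(s, 2, 10, log = TRUE))
  Z <- integrate(post_un, 0, 5)$value
  oracle_mean <- integrate(function(s) s * post_un(s), 0, 5)$value / Z
  st <- mcmc_settings(n_generations = 30000, sample_every = 10, n_chains = 1,
                      seed = 9)
  run <- mcmc_run(m, jc, settings = st, n_runs = 1)[[1]]
  path <- vapply(run$trees, function(tr) sum(tr$edge.length), 1)
  post <- path[-seq_len(750)]
  ac <- acf(post, plot = FALSE, lag.max = 150)$acf[-1]
  ess <- length(post) / (1 + 2 * sum(pmax(ac, 0)))
  mcse <- sd(post) / sqrt(max(ess, 10))
  expect_lte(abs(mean(post) - oracle_mean), 3 * mcse)
})
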