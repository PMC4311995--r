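test_that("discrete-gamma rates are quantile medians with mean one", {
  expect_equal(gamma_rates(0.5, 1), 1)
  r <- gamma_rates(0.37, 4)
  expect_equal(mean(r), 1)
  expect_true(all(diff(r) > 0))
  q <- qgamma((2 * (1:4) - 1) / 8, shape = 0.37, rate = 0.37)
  expect_equal(r, q / mean(q))
})

test_that("two-taxon closed forms hold at the branch-length extremes", {
  jc <- subst_model("JC69", gamma = FALSE)
  m <- rbind(A = "A", B = "A")
  tr <- ape::read.tree(text = "(A:0.0,B:0.0);")
  expect_equal(lnL_dna(tr, m, jc), log(1 / 4), tolerance = 1e-10)
  # saturation: every site pattern tends to probability 1/16
  tr2 <- ape::read.tree(text = "(A:40,B:40);")
  m2 <- rbind(A = "A", B = "C")
  expect_equal(lnL_dna(tr2, m2, jc), log(1 / 16), tolerance = 1e-6)
  expect_equal(lnL_dna(tr2, rbind(A = "G", B = "G"), jc), log(1 / 16),
               tolerance = 1e-6)
})

test_that("pruning equals phangorn on a GTR instance (independent oracle)", {
  skip_if_not_installed("phangorn")
  set.seed(17)
  mod <- subst_model("GTR", rates = c(1.2, 3, 0.8, 1.1, 2.5, 1),
                     freqs = c(.3, .2, .25, .25), gamma = FALSE)
  tr <- ape::unroot(ape::rtree(5))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.4)
  m <- sim_seqs(tr, 60, mod)
  fit <- phangorn::pml(tr, phangorn::phyDat(m), bf = mod$freqs,
                       Q = mod$rates, k = 1)
  expect_equal(lnL_dna(tr, m, mod), fit$logLik, tolerance = 1e-8)
})

test_that("gaps and N are marginalised as missing data", {
  jc <- subst_model("JC69", gamma = FALSE)
  tr <- ape::read.tree(text = "(A:0.1,B:0.2,C:0.15);")
  m <- rbind(A = c("A", "-"), B = c("C", "N"), C = c("G", "G"))
  # a column that is all-missing except one tip contributes the marginal of
  # a single observation: 1/4 under JC
  m2 <- rbind(A = c("A", "-"), B = c("C", "-"), C = c("G", "G"))
  expect_equal(lnL_dna(tr, m2, jc) - lnL_dna(tr, m2[, 1, drop = FALSE], jc),
               log(1 / 4), tolerance = 1e-10)
  expect_error(lnL_dna(tr, rbind(X = "A", B = "C", C = "G"), jc), "missing")
  expect_true(is.finite(lnL_dna(tr, m, jc)))
})

test_that("binary variable-coding identity and '?' marginalisation hold", {
  tr <- ape::unroot(ape::rtree(4))
  tr$edge.length <- c(0.2, 0.1, 0.3, 0.15, 0.25)
  tips <- tr$tip.label
  st <- matrix(c("0", "1", "1", "0",
                 "1", "0", "?", "0",
                 "0", "0", "1", "1"), 4, 3,
               dimnames = list(tips, NULL))
  sic <- list(ids = tips, events = data.frame(start = 0:2, end = 1:3),
              states = st, constant = rep(FALSE, 3))
  bmv <- binary_model(freqs = c(.6, .4), gamma = TRUE, alpha = .7,
                      conditioning = "variable")
  bmn <- binary_model(freqs = c(.6, .4), gamma = TRUE, alpha = .7,
                      conditioning = "none")
  lv <- lnL_binary(tr, sic, bmv)
  ln <- lnL_binary(tr, sic, bmn)
  pv <- p_variable(tr, bmv)
  expect_equal(lv + ncol(st) * log(pv), ln, tolerance = 1e-10)
  # '?' equals the sum of the two resolved likelihoods
  s1 <- sic; s1$states <- st[, 2, drop = FALSE]; s1$constant <- FALSE
  s1$events <- sic$events[2, ]
  r0 <- s1; r0$states[3, 1] <- "0"
  r1 <- s1; r1$states[3, 1] <- "1"
  expect_equal(exp(lnL_binary(tr, s1, bmn)),
               exp(lnL_binary(tr, r0, bmn)) + exp(lnL_binary(tr, r1, bmn)),
               tolerance = 1e-12)
  # all-constant matrix under variable coding is rejected
  cst <- sic
  cst$states <- matrix("1", 4, 1, dimnames = list(tips, NULL))
  cst$constant <- TRUE
  expect_error(lnL_binary(tr, cst, bmv), "variable")
})

test_that("conditioned two-tip single character matches hand enumeration", {
  # symmetric frequencies, tips (0, 1): the variable patterns are (0,1) and
  # (1,0) with equal probability, so the conditioned likelihood is 1/2
  tr <- ape::read.tree(text = "(A:0.3,B:0.3);")
  sic <- list(ids = c("A", "B"), events = data.frame(start = 0, end = 1),
              states = matrix(c("0", "1"), 2, 1,
                              dimnames = list(c("A", "B"), NULL)),
              constant = FALSE)
  bm <- binary_model(freqs = c(.5, .5), gamma = FALSE,
                     conditioning = "variable")
  expect_equal(exp(lnL_binary(tr, sic, bm)), 0.5, tolerance = 1e-10)
})
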