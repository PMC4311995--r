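# Metropolis-coupled Bayesian MCMC over trees, branch lengths and model
# parameters, with split-frequency convergence diagnostics (ASDSF),
# majority-rule consensus, and molecular-outgroup rooting.
#
# Priors (MrBayes-like defaults, configurable here only through code):
# branch lengths iid Exponential(10), flat Dirichlet on GTR
# exchangeabilities and base/binary frequencies, Exponential(1) on the
# gamma shapes.  Chain i is heated with beta_i = 1/(1 + lambda*i).

#' MCMC settings
#'
#' @param n_generations total generations (divisible by `sample_every`).
#' @param sample_every sampling interval for the cold chain.
#' @param n_chains number of Metropolis-coupled chains (1 = plain MH).
#' @param burnin_frac fraction of samples discarded by consumers.
#' @param heat_lambda heating increment; `beta_i = 1/(1 + heat_lambda * i)`.
#' @param seed RNG seed.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_generations = 2e6, sample_every = 100L,
                          n_chains = 4L, burnin_frac = 0.25,
                          heat_lambda = 0.1, seed = 1L) {
  stopifnot(n_generations %% sample_every == 0,
            burnin_frac >= 0, burnin_frac < 1, n_chains >= 1L)
  structure(list(n_generations = as.numeric(n_generations),
                 sample_every = as.integer(sample_every),
                 n_chains = as.integer(n_chains),
                 burnin_frac = burnin_frac, heat_lambda = heat_lambda,
                 seed = as.integer(seed)), class = "mcmc_settings")
}

# log prior of a chain state
.log_prior <- function(st) {
  lp <- sum(dexp(st$tree$edge.length, rate = 10, log = TRUE))
  lp + dexp(st$alpha, 1, log = TRUE) +
    if (!is.null(st$balpha)) dexp(st$balpha, 1, log = TRUE) else 0
}

# Dirichlet proposal density (log), concentration conc*x
.ldirich <- function(x, a) {
  sum((a - 1) * log(x)) + lgamma(sum(a)) - sum(lgamma(a))
}

.rdirich <- function(a) {
  g <- rgamma(length(a), shape = a)
  g / sum(g)
}

#' Run the Bayesian MCMC
#'
#' Metropolis-coupled MCMC over topology (NNI), branch lengths
#' (multiplier), GTR exchangeabilities and frequencies (Dirichlet
#' proposals), gamma shapes (multiplier), and the binary partition's
#' frequencies when present.  Returns `n_runs` independent runs (distinct
#' seed offsets), each a `tree_sample`.
#'
#' @inheritParams ml_search
#' @param settings an [mcmc_settings()].
#' @param n_runs number of independent runs.
#' @return A list of `tree_sample` objects (fields `gen`, `trees`, `lnL`,
#'   `alpha`, `settings`).
#' @export
mcmc_run <- function(aln, model = subst_model(), sic = NULL,
                     bin_model = binary_model(), settings = mcmc_settings(),
                     n_runs = 2L) {
  m <- if (is.matrix(aln)) aln else as.matrix(aln)
  lapply(seq_len(n_runs), function(r)
    .mcmc_one(m, model, sic, bin_model, settings,
              seed = settings$seed + 1000L * (r - 1L), run_id = r))
}

.mcmc_one <- function(m, model, sic, bin_model, settings, seed, run_id) {
  with_seed(seed, {
    nch <- settings$n_chains
    beta <- 1 / (1 + settings$heat_lambda * (seq_len(nch) - 1))
    has_bin <- !is.null(sic)
    start_tree <- function() {
      tr <- if (nrow(m) >= 3L)
        ape::rtree(nrow(m), tip.label = sample(rownames(m)), rooted = FALSE)
      else ape::read.tree(text = paste0("(", rownames(m)[1], ":0.05,",
                                        rownames(m)[2], ":0.05);"))
      tr$edge.length <- rexp(nrow(tr$edge), 10)
      tr
    }
    init_state <- function() {
      md <- model
      st <- list(tree = start_tree(), rates = md$rates / sum(md$rates),
                 freqs = md$freqs, alpha = md$alpha,
                 bfreqs = if (has_bin) bin_model$freqs,
                 balpha = if (has_bin) bin_model$alpha)
      st
    }
    ddata <- .compress_dna(m)
    if (has_bin) {
      bdata <- .compress_binary(sic, drop_constant =
                                  bin_model$conditioning == "variable")
      if (ncol(bdata$pat) == 0L) { has_bin <- FALSE; sic <- NULL }
      nt_ <- nrow(m)
      cdata <- list(pat = matrix(c(rep(1L, nt_), rep(2L, nt_)), nt_, 2,
                                 dimnames = list(rownames(m), NULL)),
                    w = c(1, 1), ids = rownames(m))
    }
    lnl_state <- function(st) {
      md <- model
      md$rates <- st$rates / st$rates[6]
      md$freqs <- st$freqs
      md$alpha <- st$alpha
      pr <- .prune(st$tree, ddata, .model_eigen(md), .model_rates(md))
      ll <- sum(ddata$w * log(pr$site))
      if (has_bin) {
        bm <- bin_model
        bm$freqs <- st$bfreqs; bm$alpha <- st$balpha
        beig <- .model_eigen(bm); brts <- .model_rates(bm)
        pb <- .prune(st$tree, bdata, beig, brts)
        ll <- ll + sum(bdata$w * log(pb$site))
        if (bm$conditioning == "variable") {
          pc <- .prune(st$tree, cdata, beig, brts)
          ll <- ll - sum(bdata$w) * log(1 - sum(pc$site))
        }
      }
      ll
    }
    chains <- lapply(seq_len(nch), function(i) {
      st <- init_state()
      st$lnL <- lnl_state(st)
      st$lpri <- .log_prior(st)
      st
    })
    can_nni <- nrow(m) >= 4L
    kinds <- c(if (can_nni) "nni", "brlen", "rates", "freqs", "alpha",
               if (has_bin) c("bfreqs", "balpha"))
    wts <- c(if (can_nni) 3, 4, if (model$kind == "GTR") 1 else 0,
             if (model$kind %in% c("GTR", "HKY85")) 1 else 0, 1,
             if (has_bin) c(1, 1))
    keep <- wts > 0
    kinds <- kinds[keep]; wts <- wts[keep]
    propose <- function(st) {
      kind <- sample(kinds, 1, prob = wts)
      lhast <- 0
      if (kind == "nni") {
        st$tree <- .nni_random(st$tree)
      } else if (kind == "brlen") {
        k <- sample.int(nrow(st$tree$edge), 1)
        fac <- exp(0.5 * (runif(1) - 0.5))
        st$tree$edge.length[k] <- st$tree$edge.length[k] * fac
        lhast <- log(fac)
      } else if (kind == "rates") {
        conc <- 300
        new <- .rdirich(conc * st$rates)
        lhast <- .ldirich(st$rates, conc * new) - .ldirich(new, conc * st$rates)
        st$rates <- new
      } else if (kind == "freqs") {
        conc <- 300
        new <- .rdirich(conc * st$freqs)
        lhast <- .ldirich(st$freqs, conc * new) - .ldirich(new, conc * st$freqs)
        st$freqs <- new
      } else if (kind == "alpha") {
        fac <- exp(0.4 * (runif(1) - 0.5))
        st$alpha <- st$alpha * fac
        lhast <- log(fac)
      } else if (kind == "bfreqs") {
        conc <- 100
        new <- .rdirich(conc * st$bfreqs)
        lhast <- .ldirich(st$bfreqs, conc * new) - .ldirich(new, conc * st$bfreqs)
        st$bfreqs <- new
      } else if (kind == "balpha") {
        fac <- exp(0.4 * (runif(1) - 0.5))
        st$balpha <- st$balpha * fac
        lhast <- log(fac)
      }
      st$lnL <- lnl_state(st)
      st$lpri <- .log_prior(st)
      list(state = st, lhast = lhast)
    }
    nsamp <- settings$n_generations / settings$sample_every
    gen <- numeric(nsamp); lls <- numeric(nsamp); alphas <- numeric(nsamp)
    trees <- vector("list", nsamp)
    si <- 0L
    for (g in seq_len(settings$n_generations)) {
      for (i in seq_len(nch)) {
        pr <- propose(chains[[i]])
        lr <- beta[i] * ((pr$state$lnL + pr$state$lpri) -
                         (chains[[i]]$lnL + chains[[i]]$lpri)) + pr$lhast
        if (is.finite(lr) && log(runif(1)) < lr) chains[[i]] <- pr$state
      }
      if (nch > 1L) {
        i <- sample.int(nch - 1L, 1)
        lr <- (beta[i] - beta[i + 1]) *
          ((chains[[i + 1]]$lnL + chains[[i + 1]]$lpri) -
           (chains[[i]]$lnL + chains[[i]]$lpri))
        if (log(runif(1)) < lr) {
          tmp <- chains[[i]]; chains[[i]] <- chains[[i + 1]]; chains[[i + 1]] <- tmp
        }
      }
      if (g %% settings$sample_every == 0) {
        si <- si + 1L
        gen[si] <- g
        trees[[si]] <- chains[[1]]$tree
        lls[si] <- chains[[1]]$lnL
        alphas[si] <- chains[[1]]$alpha
      }
    }
    structure(list(gen = gen, trees = trees, lnL = lls, alpha = alphas,
                   run_id = run_id, seed = seed, settings = settings),
              class = "tree_sample")
  })
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("tree_sample: run", x$run_id, "-", length(x$trees), "samples, lnL range [",
      sprintf("%.2f", min(x$lnL)), ",", sprintf("%.2f", max(x$lnL)), "]\n")
  invisible(x)
}

# post-burn-in tree list of a sample (first floor(frac*N) discarded)
.post_burnin <- function(sample, burnin_frac) {
  n <- length(sample$trees)
  drop <- floor(burnin_frac * n)
  if (drop >= n) stop("no post-burn-in samples")
  sample$trees[(drop + 1L):n]
}

# split frequency table of a tree list
.split_freqs <- function(trees) {
  counts <- new.env(parent = emptyenv())
  for (tr in trees) for (k in names(.tree_splits(tr)$internal))
    assign(k, (get0(k, counts, inherits = FALSE) %||% 0) + 1, counts)
  ks <- ls(counts)
  setNames(vapply(ks, function(k) get(k, counts), 1) / length(trees), ks)
}

#' Average standard deviation of split frequencies between two runs
#'
#' Over splits reaching at least `min_freq` in either run (post burn-in),
#' the mean of the standard deviations of the two split frequencies.
#'
#' @param runA,runB `tree_sample` objects over the same taxa.
#' @param burnin_frac burn-in fraction.
#' @param min_freq inclusion threshold.
#' @return A non-negative number (0 when the runs agree exactly).
#' @export
asdsf <- function(runA, runB, burnin_frac = 0.25, min_freq = 0.10) {
  fa <- .split_freqs(.post_burnin(runA, burnin_frac))
  fb <- .split_freqs(.post_burnin(runB, burnin_frac))
  keys <- union(names(fa)[fa >= min_freq], names(fb)[fb >= min_freq])
  if (!length(keys)) return(0)
  mean(vapply(keys, function(k) {
    x <- c(fa[k] %||% 0, fb[k] %||% 0)
    x[is.na(x)] <- 0
    sd(x)
  }, 1))
}

#' Majority-rule consensus tree with posterior probabilities
#'
#' Pools post-burn-in trees from one or more runs, retains splits with
#' frequency strictly > 0.5 (no greedy compatible addition), labels them
#' with their frequencies (BPP) and assigns each retained branch the mean
#' length over the trees containing it.
#'
#' @param samples a `tree_sample` or list of them.
#' @param burnin_frac burn-in fraction applied to each run.
#' @return A `phylo` with `node.label` = BPP.
#' @export
majority_consensus <- function(samples, burnin_frac = 0.25) {
  if (inherits(samples, "tree_sample")) samples <- list(samples)
  trees <- do.call(c, lapply(samples, .post_burnin, burnin_frac = burnin_frac))
  n <- length(trees)
  all_tips <- sort(trees[[1]]$tip.label)
  cnt <- new.env(parent = emptyenv()); lensum <- new.env(parent = emptyenv()); pendsum <- new.env(parent = emptyenv())
  sides <- list()
  for (tr in trees) {
    sp <- .tree_splits(tr)
    for (k in names(sp$internal)) {
      assign(k, (get0(k, cnt, inherits = FALSE) %||% 0) + 1, cnt)
      assign(k, (get0(k, lensum, inherits = FALSE) %||% 0) + sp$internal[[k]], lensum)
      sides[[k]] <- sp$sides[[k]]
    }
    for (tp in names(sp$pendant))
      assign(tp, (get0(tp, pendsum, inherits = FALSE) %||% 0) + sp$pendant[[tp]], pendsum)
  }
  ks <- ls(cnt)
  freq <- vapply(ks, function(k) get(k, cnt), 1) / n
  keep <- ks[freq > 0.5]
  clades <- lapply(keep, function(k) sides[[k]])
  clade_len <- vapply(keep, function(k) get(k, lensum) / get(k, cnt), 1)
  clade_lab <- setNames(sprintf("%.4f", freq[keep]), keep)
  tip_len <- lapply(setNames(all_tips, all_tips),
                    function(tp) get(tp, pendsum) / n)
  tree <- .tree_from_clades(all_tips, clades, clade_len = unname(clade_len),
                            clade_lab = unname(vapply(keep, function(k)
                              clade_lab[[k]], "")), tip_len = tip_len)
  attr(tree, "support_scale") <- "bpp"
  attr(tree, "split_freqs") <- setNames(freq, ks)
  tree
}

#' Root a tree on an outgroup clade
#'
#' Places the root on the branch defining the outgroup split (at its
#' midpoint).  Errors — never forces — when the outgroup is not
#' monophyletic, reporting the smallest clade containing it.
#'
#' @param tree an unrooted `phylo`.
#' @param outgroup_ids non-empty proper subset of tip labels.
#' @return A rooted `phylo`; ingroup splits are preserved.
#' @export
root_on_clade <- function(tree, outgroup_ids) {
  tips <- tree$tip.label
  stopifnot(length(outgroup_ids) >= 1L, all(outgroup_ids %in% tips),
            length(outgroup_ids) < length(tips))
  og <- sort(unique(outgroup_ids))
  sp <- .tree_splits(tree)
  is_og_split <- function(side) setequal(side, og) ||
    setequal(setdiff(tips, side), og)
  stem_len <- NA_real_
  if (length(og) == 1L) {
    stem_len <- sp$pendant[[og]]
  } else {
    hit <- names(sp$internal)[vapply(names(sp$internal), function(k)
      is_og_split(sp$sides[[k]]), TRUE)]
    if (!length(hit)) {
      sets <- .node_tipsets(tree)
      sizes <- vapply(sets, length, 1L)
      cand <- which(vapply(sets, function(s) all(og %in% s), TRUE))
      smallest <- sets[[cand[which.min(sizes[cand])]]]
      stop("outgroup not monophyletic; smallest containing clade: {",
           paste(sort(smallest), collapse = ", "), "}")
    }
    stem_len <- sp$internal[[hit[1]]]
  }
  ing <- setdiff(tips, og)
  half <- (if (is.na(stem_len)) 0 else stem_len) / 2
  # clades of one root-side: each split contributes whichever of its two
  # sides is a proper subset of `side` (the split's own branch excluded)
  inner_of <- function(side) {
    out <- list(); lens <- numeric(0)
    for (k in names(sp$internal)) {
      s <- sp$sides[[k]]
      cand <- if (all(s %in% side)) s
              else { cp <- setdiff(tips, s); if (all(cp %in% side)) cp else NULL }
      if (is.null(cand) || length(cand) >= length(side)) next
      out[[length(out) + 1L]] <- sort(cand)
      lens <- c(lens, sp$internal[[k]])
    }
    list(clades = out, lens = lens)
  }
  side_tree <- function(side) {
    pend <- as.list(sp$pendant[side])
    if (length(side) == 1L)
      return(paste0(side[1], ":", sprintf("%.10g", pend[[1]])))
    inner <- inner_of(side)
    frag <- .newick_fragment(side, inner$clades, clade_len = inner$lens,
                             tip_len = pend)
    paste0("(", frag, ")")
  }
  og_part <- if (length(og) == 1L) og[1] else side_tree(og)
  txt <- paste0("(", og_part, ":", sprintf("%.10g", half), ",",
                side_tree(ing), ":", sprintf("%.10g", half), ");")
  ape::read.tree(text = txt)
}

#' Does some split separate two tip sets exactly?
#'
#' @param tree a `phylo`.
#' @param set1,set2 disjoint tip sets covering all tips.
#' @return `TRUE` iff the tree has a branch whose removal separates `set1`
#'   from `set2` (reciprocal monophyly).
#' @export
check_reciprocal_monophyly <- function(tree, set1, set2) {
  tips <- tree$tip.label
  stopifnot(setequal(c(set1, set2), tips), !length(intersect(set1, set2)))
  if (length(set1) <= 1L || length(set2) <= 1L) return(TRUE)  # trivial split
  sp <- .tree_splits(tree)
  any(vapply(sp$sides, function(s)
    setequal(s, sort(set1)) || setequal(s, sort(set2)), TRUE))
}

#' @importFrom stats dexp
NULL
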