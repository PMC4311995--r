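# Maximum-likelihood tree estimation: neighbour-joining start, NNI hill
# climbing with per-branch Brent optimisation, nonparametric bootstrap, and
# AIC model choice on a fixed evaluation tree.

# JC-corrected distance matrix from an alignment
.jc_dist <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- .pdist(m[i, ], m[j, ])
    if (is.na(p)) p <- 0.7
    p <- min(p, 0.74)
    D[i, j] <- D[j, i] <- -0.75 * log(1 - 4 * p / 3)
  }
  D
}

#' Neighbour-joining starting tree (JC distances)
#'
#' @param aln a [ribo_alignment] or character matrix.
#' @return An unrooted `phylo`; negative NJ branch lengths are clamped.
#' @export
nj_start <- function(aln) {
  m <- if (is.matrix(aln)) aln else as.matrix(aln)
  tr <- ape::nj(.jc_dist(m))
  tr$edge.length[tr$edge.length < 1e-6] <- 1e-6
  tr
}

# combined-likelihood closure over both partitions
.make_lnl <- function(aln, model, sic = NULL, bin_model = NULL) {
  data <- .compress_dna(aln)
  eig <- .model_eigen(model)
  rates <- .model_rates(model)
  bdata <- NULL
  if (!is.null(sic)) {
    drop_const <- bin_model$conditioning == "variable"
    bdata <- .compress_binary(sic, drop_constant = drop_const)
    if (ncol(bdata$pat) == 0L) bdata <- NULL
    beig <- .model_eigen(bin_model)
    brates <- .model_rates(bin_model)
  }
  function(phy) {
    pr <- .prune(phy, data, eig, rates)
    ll <- sum(data$w * log(pr$site))
    if (!is.null(bdata)) {
      pb <- .prune(phy, bdata, beig, brates)
      llb <- sum(bdata$w * log(pb$site))
      if (bin_model$conditioning == "variable") {
        nt <- length(phy$tip.label)
        cd <- list(pat = matrix(c(rep(1L, nt), rep(2L, nt)), nt, 2,
                                dimnames = list(phy$tip.label, NULL)),
                   w = c(1, 1), ids = phy$tip.label)
        pc <- .prune(phy, cd, beig, brates)
        llb <- llb - sum(bdata$w) * log(1 - sum(pc$site))
      }
      ll <- ll + llb
    }
    ll
  }
}

# one sweep of per-branch Brent optimisation; returns updated tree + lnL
.optimize_branches <- function(phy, lnl, max_bl = 10, tol = 1e-4) {
  for (k in seq_len(nrow(phy$edge))) {
    f <- function(t) {
      phy$edge.length[k] <- t
      lnl(phy)
    }
    op <- optimize(f, interval = c(1e-9, max_bl), maximum = TRUE, tol = tol)
    phy$edge.length[k] <- op$maximum
  }
  list(tree = phy, lnL = lnl(phy))
}

#' Maximum-likelihood tree search
#'
#' Starts from the NJ tree, alternates full branch-length optimisation
#' sweeps with NNI moves, accepting the best improving neighbour until no
#' move improves the combined log-likelihood by more than `tol`.
#' Deterministic given the data and tie rule (first-best in canonical split
#' order).
#'
#' @param aln a [ribo_alignment] of >= 4 sequences.
#' @param model a [subst_model()].
#' @param sic optional [sic_code()] binary partition.
#' @param bin_model a [binary_model()] for the binary partition.
#' @param start optional starting `phylo` (default NJ).
#' @param tol lnL improvement threshold.
#' @param max_moves cap on accepted NNI moves.
#' @return List with `tree` (unrooted `phylo`) and `lnL`.
#' @export
ml_search <- function(aln, model = subst_model(), sic = NULL,
                      bin_model = binary_model(), start = NULL,
                      tol = 1e-6, max_moves = 50L) {
  m <- if (is.matrix(aln)) aln else as.matrix(aln)
  if (nrow(m) < 4L) stop("ml_search needs at least 4 sequences")
  lnl <- .make_lnl(m, model, sic, bin_model)
  phy <- start %||% nj_start(m)
  cur <- .optimize_branches(phy, lnl)
  for (it in seq_len(max_moves)) {
    nb <- nni_neighbors(cur$tree)
    scores <- vapply(nb, lnl, 1)
    if (!length(scores) || max(scores) <= cur$lnL + tol) {
      # re-optimised check of the single best neighbour
      if (!length(scores)) break
      best <- which.max(scores)
      cand <- .optimize_branches(nb[[best]], lnl)
      if (cand$lnL <= cur$lnL + tol) break
      cur <- cand
      next
    }
    best <- which.max(scores)
    cur <- .optimize_branches(nb[[best]], lnl)
  }
  cur
}

#' Nonparametric bootstrap support on the ML tree
#'
#' Columns are resampled within each partition (DNA columns; binary
#' characters), the ML search rerun per replicate, and split frequencies
#' mapped onto the ML tree as percentages in `$node.label`.
#'
#' @inheritParams ml_search
#' @param n_reps number of bootstrap replicates (0 = supports skipped, with
#'   a warning).
#' @param seed RNG seed.
#' @return List with `tree` (node labels = bootstrap percentages), `lnL`,
#'   and the per-split support table.
#' @export
bootstrap_support <- function(aln, model = subst_model(), sic = NULL,
                              bin_model = binary_model(), n_reps = 1000L,
                              seed = 1L) {
  m <- if (is.matrix(aln)) aln else as.matrix(aln)
  fit <- ml_search(m, model, sic, bin_model)
  if (n_reps == 0L) {
    warning("n_reps = 0: no bootstrap supports computed")
    return(list(tree = fit$tree, lnL = fit$lnL, support = NULL))
  }
  counts <- list()
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), replace = TRUE)
      mb <- m[, cols, drop = FALSE]
      sb <- NULL
      if (!is.null(sic) && nrow(sic$events)) {
        ev <- sample.int(nrow(sic$events), replace = TRUE)
        sb <- sic
        sb$events <- sic$events[ev, , drop = FALSE]
        sb$states <- sic$states[, ev, drop = FALSE]
        sb$constant <- sic$constant[ev]
      }
      ft <- ml_search(mb, model, sb, bin_model)
      for (key in names(.tree_splits(ft$tree)$internal))
        counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  })
  sp <- .tree_splits(fit$tree)
  supp <- vapply(names(sp$internal), function(k)
    100 * (counts[[k]] %||% 0) / n_reps, 1)
  lab <- setNames(sprintf("%.0f", supp), names(sp$internal))
  tree <- .tree_from_splits(sp, clade_lab = lab)
  attr(tree, "support_scale") <- "bootstrap"
  list(tree = tree, lnL = fit$lnL,
       support = data.frame(split = names(sp$internal), mlbs = unname(supp)))
}

#' AIC model selection on a fixed evaluation tree
#'
#' Fits each candidate's free parameters (exchangeabilities, base
#' frequencies, gamma shape, plus a shared branch-length scale that is not
#' counted) by numerical optimisation on the NJ tree and ranks candidates
#' by AIC = 2k - 2 lnL.
#'
#' @param aln a [ribo_alignment] or character matrix.
#' @param kinds model kinds to try.
#' @param gamma gamma options to try (one or both of `FALSE`, `TRUE`).
#' @param tree optional fixed evaluation tree (default NJ).
#' @return List with `best` (a fitted [subst_model()]), `table` (per
#'   candidate: kind, gamma, k, lnL, AIC, converged) and `tree`.
#' @export
model_select_aic <- function(aln, kinds = c("JC69", "K80", "HKY85", "GTR"),
                             gamma = c(FALSE, TRUE), tree = NULL) {
  m <- if (is.matrix(aln)) aln else as.matrix(aln)
  phy <- tree %||% nj_start(m)
  data <- .compress_dna(m)
  emp <- table(factor(m[m %in% c("A", "C", "G", "T")], levels = c("A", "C", "G", "T")))
  emp_f <- pmax(as.vector(emp) / sum(emp), 1e-3); emp_f <- emp_f / sum(emp_f)
  rows <- list(); fits <- list()
  for (kind in kinds) for (g in gamma) {
    k_rates <- switch(kind, JC69 = 0L, K80 = 1L, HKY85 = 1L, GTR = 5L)
    k_freq <- switch(kind, JC69 = 0L, K80 = 0L, HKY85 = 3L, GTR = 3L)
    k <- k_rates + k_freq + if (g) 1L else 0L
    # parameter vector: [log rates (k_rates)] [freq logits (k_freq)]
    #                   [log alpha (if g)] [log branch scale]
    unpack <- function(p) {
      i <- 0L
      rates <- rep(1, 6)
      if (kind == "K80" || kind == "HKY85") {
        rates[c(2, 5)] <- exp(p[1]); i <- 1L
      } else if (kind == "GTR") {
        rates[1:5] <- exp(p[1:5]); i <- 5L
      }
      freqs <- if (k_freq) {
        e <- exp(c(p[(i + 1):(i + 3)], 0)); e / sum(e)
      } else rep(0.25, 4)
      i <- i + k_freq
      alpha <- if (g) exp(p[i + 1L]) else 1
      if (g) i <- i + 1L
      scale <- exp(p[i + 1L])
      list(model = subst_model(kind, rates = rates, freqs = freqs,
                               gamma = g, alpha = alpha),
           scale = scale)
    }
    nll <- function(p) {
      u <- unpack(p)
      ph <- phy; ph$edge.length <- ph$edge.length * u$scale
      eig <- .model_eigen(u$model)
      pr <- .prune(ph, data, eig, .model_rates(u$model))
      -sum(data$w * log(pr$site))
    }
    p0 <- c(rep(0, k_rates),
            if (k_freq) log(emp_f[1:3] / emp_f[4]) else NULL,
            if (g) log(0.5) else NULL,
            0)
    op <- tryCatch({
      o1 <- optim(p0, nll, method = "BFGS",
                  control = list(maxit = 300, reltol = 1e-10))
      # polish (and rescue) with a restarted simplex
      o2 <- optim(o1$par, nll, method = "Nelder-Mead",
                  control = list(maxit = 1000, reltol = 1e-10,
                                 warn.1d.NelderMead = FALSE))
      if (o2$value < o1$value) o2 else o1
    }, error = function(e) NULL)
    converged <- !is.null(op) && op$convergence == 0L
    ll <- if (is.null(op)) -Inf else -op$value
    rows[[length(rows) + 1L]] <- data.frame(
      kind = kind, gamma = g, k = k, lnL = ll,
      AIC = 2 * k - 2 * ll, converged = converged)
    fits[length(fits) + 1L] <- list(if (is.null(op)) NULL
                                    else unpack(op$par)$model)
  }
  tab <- do.call(rbind, rows)
  best <- which.min(tab$AIC)
  list(best = fits[[best]], table = tab[order(tab$AIC), ], tree = phy)
}
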