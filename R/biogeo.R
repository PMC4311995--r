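# Bayesian binary MCMC (BBM) ancestral-range reconstruction.  Each
# geographic area is an independent two-state presence/absence character
# evolving under an F81-style binary CTMC with discrete-gamma rate
# variation.  Over a posterior tree sample, model parameters are sampled by
# a (optionally Metropolis-coupled) MCMC and node states drawn by pruning
# plus stochastic traceback; per-node range (area-subset) probabilities are
# aggregated across trees and samples, nodes matched by tip set.

#' Read / construct an area presence matrix
#'
#' @param table a TSV path or data frame with columns `taxon` and `areas`
#'   (strings of area letters, e.g. `"A"` or `"BC"`).
#' @param areas ordered area labels.
#' @param taxa optional tip set that must all be present.
#' @return Logical matrix (taxa x areas) of class `area_matrix`.
#' @export
code_areas <- function(table, areas = c("A", "B", "C"), taxa = NULL) {
  df <- if (is.character(table))
    read.table(table, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  else as.data.frame(table)
  stopifnot(all(c("taxon", "areas") %in% names(df)))
  if (!is.null(taxa)) {
    miss <- setdiff(taxa, df$taxon)
    if (length(miss)) stop("missing taxa in area table: ",
                           paste(miss, collapse = ", "))
  }
  m <- matrix(FALSE, nrow(df), length(areas),
              dimnames = list(df$taxon, areas))
  for (i in seq_len(nrow(df))) {
    ltr <- .s2v(toupper(df$areas[i]))
    bad <- setdiff(ltr, areas)
    if (length(bad)) stop("unknown area letter '", bad[1], "' for taxon ",
                          df$taxon[i])
    if (!length(ltr)) stop("taxon ", df$taxon[i], " has no area")
    m[i, ltr] <- TRUE
  }
  structure(m, class = c("area_matrix", "matrix"))
}

#' BBM settings
#'
#' @param n_chains Metropolis-coupled chains for the parameter MCMC.
#' @param temperature heating increment (`beta_i = 1/(1 + temperature*i)`).
#' @param n_generations total generations (over all trees).
#' @param sample_every sampling interval.
#' @param burnin_samples samples discarded as burn-in.
#' @param max_areas maximum ancestral range size reported.
#' @param seed RNG seed.
#' @return A list of class `bbm_settings`.
#' @export
bbm_settings <- function(n_chains = 4L, temperature = 0.1,
                         n_generations = 2e6, sample_every = 100L,
                         burnin_samples = 5000L, max_areas = 3L, seed = 1L) {
  total <- n_generations / sample_every
  stopifnot(burnin_samples < total, max_areas >= 1L)
  structure(list(n_chains = as.integer(n_chains), temperature = temperature,
                 n_generations = as.numeric(n_generations),
                 sample_every = as.integer(sample_every),
                 burnin_samples = as.integer(burnin_samples),
                 max_areas = as.integer(max_areas), seed = as.integer(seed)),
            class = "bbm_settings")
}

# pruning partials for one binary character on a rooted tree; returns
# per-node conditional likelihood matrices for one gamma category rate
.bin_partials <- function(phy, tipstate, eig, r) {
  nt <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  L <- vector("list", nt + phy$Nnode)
  for (i in seq_len(nt)) {
    s <- tipstate[phy$tip.label[i]]
    L[[i]] <- if (is.na(s)) c(1, 1) else { v <- c(0, 0); v[s + 1L] <- 1; v }
  }
  P <- vector("list", nrow(po$edge))
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    P[[k]] <- .pmat(eig, po$edge.length[k], r)
    contrib <- as.vector(P[[k]] %*% L[[ch]])
    L[[p]] <- if (is.null(L[[p]])) contrib else L[[p]] * contrib
  }
  list(L = L, P = P, edge = po$edge, root = po$edge[nrow(po$edge), 1])
}

# sample states at all nodes for one character by stochastic traceback;
# returns integer vector over nodes (0/1), tips included
.sample_states <- function(bp, freqs, nt, nnode) {
  root <- bp$root
  st <- integer(nt + nnode)
  pr <- freqs * bp$L[[root]]
  st[root] <- as.integer(runif(1) < pr[2] / sum(pr))
  # preorder = reverse postorder edge order
  for (k in rev(seq_len(nrow(bp$edge)))) {
    p <- bp$edge[k, 1]; ch <- bp$edge[k, 2]
    w <- bp$P[[k]][st[p] + 1L, ] * bp$L[[ch]]
    st[ch] <- as.integer(runif(1) < w[2] / sum(w))
  }
  st
}

#' Bayesian binary MCMC ancestral-range reconstruction
#'
#' @param trees rooted trees containing only ingroup (e.g. functional) tips:
#'   a `multiPhylo`, list of `phylo`, or single `phylo`.  Outgroups must
#'   already be removed and any tree-sample burn-in already discarded.
#' @param areas an [code_areas()] matrix covering all tips.
#' @param settings a [bbm_settings()].
#' @return A list of class `range_posterior`: per node (keyed by tip-set
#'   clade) the probability of each area subset of size `<= max_areas`, its
#'   coverage fraction across trees, and bookkeeping.
#' @export
bbm_ancestral <- function(trees, areas, settings = bbm_settings()) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  nt_trees <- length(trees)
  tips <- trees[[1]]$tip.label
  stopifnot(all(tips %in% rownames(areas)))
  A <- ncol(areas)
  area_names <- colnames(areas)
  total <- settings$n_generations / settings$sample_every
  keep_per <- max(1L, ceiling((total - settings$burnin_samples) / nt_trees))
  burn_per <- max(1L, ceiling(settings$burnin_samples / nt_trees))
  nch <- settings$n_chains
  beta <- 1 / (1 + settings$temperature * (seq_len(nch) - 1))
  counts <- new.env(parent = emptyenv()); seen <- new.env(parent = emptyenv()); empties <- new.env(parent = emptyenv())
  with_seed(settings$seed, {
    for (ti in seq_len(nt_trees)) {
      phy <- trees[[ti]]
      phy$edge.length[phy$edge.length < 1e-9] <- 1e-9
      ntp <- length(phy$tip.label)
      sets <- .node_tipsets(phy)
      node_keys <- vapply((ntp + 1L):(ntp + phy$Nnode), function(nd)
        paste(sort(sets[[nd]]), collapse = "|"), "")
      for (k in node_keys) assign(k, (get0(k, seen, inherits = FALSE) %||% 0) + 1, seen)
      tipmat <- areas[phy$tip.label, , drop = FALSE]
      # chain states: per-area stationary presence frequency + gamma shape
      init <- function() {
        f <- pmin(pmax(colMeans(tipmat), 0.1), 0.9)
        list(f = f, alpha = 1)
      }
      loglik <- function(st) {
        ll <- 0
        for (a in seq_len(A)) {
          eig <- .model_eigen(binary_model(freqs = c(1 - st$f[a], st$f[a]),
                                           gamma = FALSE))
          rts <- gamma_rates(st$alpha, 4L)
          ts <- setNames(as.integer(tipmat[, a]), phy$tip.label)
          lk <- mean(vapply(rts, function(r) {
            bp <- .bin_partials(phy, ts, eig, r)
            sum(c(1 - st$f[a], st$f[a]) * bp$L[[bp$root]])
          }, 1))
          ll <- ll + log(lk)
        }
        ll
      }
      chains <- lapply(seq_len(nch), function(i) {
        st <- init(); st$ll <- loglik(st); st
      })
      lprior <- function(st) dexp(st$alpha, 1, log = TRUE)  # flat on f
      for (it in seq_len(burn_per + keep_per)) {
        for (i in seq_len(nch)) {
          st <- chains[[i]]
          u <- runif(1)
          if (u < 0.35) {
            # independence draw from the flat prior (Hastings ratio 1):
            # with weak tip data this decorrelates the frequency chain
            a <- sample.int(A, 1)
            f2 <- st$f; f2[a] <- runif(1, 0.01, 0.99)
            cand <- st; cand$f <- f2
          } else if (u < 0.7) {
            a <- sample.int(A, 1)
            f2 <- st$f; f2[a] <- f2[a] + 0.25 * (runif(1) - 0.5)
            if (f2[a] <= 0.01 || f2[a] >= 0.99) next
            cand <- st; cand$f <- f2
          } else {
            fac <- exp(0.4 * (runif(1) - 0.5))
            cand <- st; cand$alpha <- st$alpha * fac
          }
          cand$ll <- loglik(cand)
          lr <- beta[i] * ((cand$ll + lprior(cand)) - (st$ll + lprior(st))) +
            (if (!is.null(cand$alpha) && cand$alpha != st$alpha)
               log(cand$alpha / st$alpha) else 0)
          if (is.finite(lr) && log(runif(1)) < lr) chains[[i]] <- cand
        }
        if (nch > 1L) {
          i <- sample.int(nch - 1L, 1)
          lr <- (beta[i] - beta[i + 1]) * (chains[[i + 1]]$ll - chains[[i]]$ll)
          if (log(runif(1)) < lr) {
            tmp <- chains[[i]]; chains[[i]] <- chains[[i + 1]]; chains[[i + 1]] <- tmp
          }
        }
        if (it <= burn_per) next
        # draw node states from the cold chain
        st <- chains[[1]]
        rts <- gamma_rates(st$alpha, 4L)
        node_state <- matrix(0L, phy$Nnode, A)
        for (a in seq_len(A)) {
          frq <- c(1 - st$f[a], st$f[a])
          eig <- .model_eigen(binary_model(freqs = frq, gamma = FALSE))
          ts <- setNames(as.integer(tipmat[, a]), phy$tip.label)
          bps <- lapply(rts, function(r) .bin_partials(phy, ts, eig, r))
          liks <- vapply(bps, function(bp) sum(frq * bp$L[[bp$root]]), 1)
          ci <- sample.int(length(rts), 1, prob = liks)
          stt <- .sample_states(bps[[ci]], frq, ntp, phy$Nnode)
          node_state[, a] <- stt[(ntp + 1L):(ntp + phy$Nnode)]
        }
        for (nd in seq_len(phy$Nnode)) {
          if (!any(node_state[nd, ] == 1L)) {
            k <- node_keys[nd]
            assign(k, (get0(k, empties, inherits = FALSE) %||% 0) + 1, empties)
            next                          # empty range renormalised out
          }
          subset <- paste(area_names[node_state[nd, ] == 1L], collapse = "")
          key <- paste0(node_keys[nd], "::", subset)
          assign(key, (get0(key, counts, inherits = FALSE) %||% 0) + 1, counts)
        }
      }
    }
  })
  # aggregate
  all_keys <- ls(counts)
  nodes <- unique(sub("::.*$", "", all_keys))
  post <- lapply(nodes, function(nd) {
    ks <- all_keys[startsWith(all_keys, paste0(nd, "::"))]
    subs <- sub("^.*::", "", ks)
    cnt <- vapply(ks, function(k) get(k, counts), 1)
    probs <- cnt / sum(cnt)
    # max_areas enforcement: oversized subsets redistributed to their
    # highest-marginal subsets of allowed size, proportionally
    over <- nchar(subs) > settings$max_areas
    if (any(over)) {
      marg <- vapply(area_names, function(a)
        sum(probs[grepl(a, subs, fixed = TRUE)]), 1)
      for (i in which(over)) {
        ltr <- .s2v(subs[i])
        keepA <- ltr[order(marg[ltr], decreasing = TRUE)][seq_len(settings$max_areas)]
        tgt <- paste(sort(keepA)[order(match(sort(keepA), area_names))], collapse = "")
        j <- match(tgt, subs)
        if (is.na(j)) { subs <- c(subs, tgt); probs <- c(probs, probs[i]) }
        else probs[j] <- probs[j] + probs[i]
        probs[i] <- 0
      }
      keep <- probs > 0 & !over
      subs <- subs[keep]; probs <- probs[keep]
      probs <- probs / sum(probs)
    }
    ord <- order(probs, decreasing = TRUE)
    list(node = nd,
         probs = setNames(probs[ord], subs[ord]),
         coverage = (get0(nd, seen, inherits = FALSE) %||% 0) / nt_trees,
         n_empty = get0(nd, empties, inherits = FALSE) %||% 0)
  })
  names(post) <- nodes
  structure(list(nodes = post, areas = area_names,
                 settings = settings, n_trees = nt_trees),
            class = "range_posterior")
}

#' Summarise ancestral-range posteriors as a node table
#'
#' @param posteriors a [bbm_ancestral()] result.
#' @param top number of top subsets to report per node.
#' @return Data frame: node clade, most probable range, its probability,
#'   coverage fraction, and the top subsets formatted as text.
#' @export
summarize_ranges <- function(posteriors, top = 3L) {
  rows <- lapply(posteriors$nodes, function(nd) {
    p <- nd$probs
    k <- min(top, length(p))
    data.frame(node = nd$node,
               best_range = names(p)[1],
               best_prob = unname(p[1]),
               coverage = nd$coverage,
               top_subsets = paste(sprintf("%s:%.4f", names(p)[seq_len(k)],
                                           p[seq_len(k)]), collapse = " "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-vapply(strsplit(out$node, "|", fixed = TRUE), length, 1L)), ]
}
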