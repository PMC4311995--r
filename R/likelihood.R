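# Felsenstein pruning likelihoods for the DNA (GTR family + gamma) and
# binary restriction (with variable-coding ascertainment correction)
# partitions.  Gaps, N and "?" are marginalised as missing data.  On
# unrooted trees the likelihood is invariant to root placement (pulley
# principle), which the tests assert.

# encode alignment -> list(pat: ntaxa x npat integer matrix (NA = missing),
#                          w: pattern weights, ids)
.compress_dna <- function(aln) {
  m <- if (is.matrix(aln)) aln else as.matrix(aln)
  X <- matrix(.dna_code[toupper(m)], nrow(m), ncol(m))
  rownames(X) <- rownames(m)
  key <- apply(X, 2, function(col) paste(ifelse(is.na(col), ".", col), collapse = ""))
  u <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[u])))
  list(pat = X[, u, drop = FALSE], w = w, ids = rownames(m))
}

.compress_binary <- function(sic, drop_constant = TRUE) {
  st <- sic$states
  if (drop_constant && length(sic$constant) && any(sic$constant))
    st <- st[, !sic$constant, drop = FALSE]
  X <- matrix(NA_integer_, nrow(st), ncol(st), dimnames = dimnames(st))
  X[st == "0"] <- 1L
  X[st == "1"] <- 2L
  list(pat = X, w = rep(1, ncol(X)), ids = sic$ids)
}

# core pruning: per-pattern site likelihoods averaged over rate categories.
# Returns list(site_lik, root_partials per category) for reuse.
.prune <- function(phy, data, eig, cat_rates, want_partials = FALSE) {
  nt <- length(phy$tip.label)
  ns <- length(eig$freqs)
  np <- ncol(data$pat)
  ord <- match(phy$tip.label, data$ids)
  if (anyNA(ord))
    stop("tree tips missing from data: ",
         paste(phy$tip.label[is.na(ord)], collapse = ", "))
  po <- ape::reorder.phylo(phy, "postorder")
  root <- po$edge[nrow(po$edge), 1]      # last postorder edge's parent
  site <- numeric(np)
  parts <- vector("list", length(cat_rates))
  for (ci in seq_along(cat_rates)) {
    r <- cat_rates[ci]
    L <- vector("list", nt + phy$Nnode)
    for (i in seq_len(nt)) {
      s <- data$pat[ord[i], ]
      M <- matrix(1, ns, np)
      obs <- !is.na(s)
      if (any(obs)) {
        M[, obs] <- 0
        M[cbind(s[obs], which(obs))] <- 1
      }
      L[[i]] <- M
    }
    for (k in seq_len(nrow(po$edge))) {
      p <- po$edge[k, 1]; ch <- po$edge[k, 2]
      P <- .pmat(eig, po$edge.length[k], r)
      contrib <- P %*% L[[ch]]
      L[[p]] <- if (is.null(L[[p]])) contrib else L[[p]] * contrib
    }
    parts[[ci]] <- L[[root]]
    site <- site + as.vector(eig$freqs %*% L[[root]]) / length(cat_rates)
  }
  list(site = site, partials = if (want_partials) parts)
}

#' Log-likelihood of a DNA alignment on a tree
#'
#' Felsenstein pruning under a [subst_model()] with discrete-gamma rate
#' mixture; gaps and N marginalised.
#'
#' @param tree a `phylo` whose tips match the alignment rows.
#' @param aln a [ribo_alignment] or character matrix.
#' @param model a [subst_model()].
#' @return The log-likelihood (sum over sites).
#' @export
lnL_dna <- function(tree, aln, model = subst_model()) {
  data <- .compress_dna(aln)
  eig <- .model_eigen(model)
  pr <- .prune(tree, data, eig, .model_rates(model))
  sum(data$w * log(pr$site))
}

#' Log-likelihood of a binary indel matrix on a tree
#'
#' Two-state CTMC with discrete-gamma mixture; `"?"` cells marginalised.
#' Under `conditioning = "variable"` each character's likelihood is divided
#' by the probability of being variable, `1 - P(all 0) - P(all 1)`
#' (restriction-data ascertainment correction); constant characters are
#' dropped beforehand.
#'
#' @param tree a `phylo` whose tips match the matrix rows.
#' @param sic a [sic_code()] result (or compatible list).
#' @param model a [binary_model()].
#' @return The log-likelihood.
#' @export
lnL_binary <- function(tree, sic, model = binary_model()) {
  drop_const <- model$conditioning == "variable"
  data <- .compress_binary(sic, drop_constant = drop_const)
  if (ncol(data$pat) == 0L) {
    if (drop_const) stop("no variable binary characters under variable coding")
    return(0)
  }
  eig <- .model_eigen(model)
  rates <- .model_rates(model)
  pr <- .prune(tree, data, eig, rates)
  ll <- sum(data$w * log(pr$site))
  if (drop_const) {
    nt <- length(tree$tip.label)
    const <- matrix(c(rep(1L, nt), rep(2L, nt)), nt, 2,
                    dimnames = list(tree$tip.label, NULL))
    cd <- list(pat = const, w = c(1, 1), ids = tree$tip.label)
    pc <- .prune(tree, cd, eig, rates)
    ll <- ll - sum(data$w) * log(1 - sum(pc$site))
  }
  ll
}

#' Probability that a binary character is variable on a tree
#'
#' `1 - P(all tips 0) - P(all tips 1)` under a [binary_model()] (gamma
#' mixture included); the variable-coding normaliser.
#'
#' @inheritParams lnL_binary
#' @return A probability.
#' @export
p_variable <- function(tree, model = binary_model()) {
  eig <- .model_eigen(model)
  nt <- length(tree$tip.label)
  const <- matrix(c(rep(1L, nt), rep(2L, nt)), nt, 2,
                  dimnames = list(tree$tip.label, NULL))
  cd <- list(pat = const, w = c(1, 1), ids = tree$tip.label)
  pc <- .prune(tree, cd, eig, .model_rates(model))
  1 - sum(pc$site)
}
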