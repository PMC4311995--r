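# Independent oracles used across the suite.  Each is a deliberately naive
# implementation (enumeration / brute force) kept separate from the package
# code paths it checks.

# exhaustive all-intervals Sawyer fragment score
brute_fragment <- function(mv, g) {
  n <- length(mv); best <- 0
  for (i in seq_len(n)) for (j in i:n) {
    seg <- mv[i:j]; k <- sum(seg == 0)
    sc <- sum(seg == 1) - g * k * (k + 1) / 2
    if (sc > best) best <- sc
  }
  best
}

# enumerate every nested structure (pair list) and score it with the same
# energy rules the fold DP uses; feasible for length <= 13
enum_fold <- function(v) {
  pairE <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% c("AT", "TA", "GC", "CG")) -1
    else if (key %in% c("GT", "TG")) -0.5
    else NA
  }
  structs <- function(i, j) {
    if (j - i < 4) return(list(list()))
    res <- structs(i + 1, j)
    for (k in (i + 4):j) {
      if (is.na(pairE(v[i], v[k]))) next
      inner <- structs(i + 1, k - 1)
      outer <- if (k == j) list(list()) else structs(k + 1, j)
      for (a in inner) for (b in outer)
        res[[length(res) + 1]] <- c(list(c(i, k)), a, b)
    }
    res
  }
  best <- 0
  for (st in structs(1, length(v))) {
    if (!length(st)) next
    keys <- vapply(st, function(p) paste(p, collapse = ","), "")
    e <- 0
    for (p in st) {
      e <- e + pairE(v[p[1]], v[p[2]])
      if (paste(p[1] + 1, p[2] - 1, sep = ",") %in% keys) e <- e - 1
    }
    if (e < best) best <- e
  }
  best
}

# simulate sequences down a tree under a subst_model (site-wise gamma rates)
sim_seqs <- function(tree, n, model = subst_model("JC69", gamma = FALSE)) {
  eig <- ribosort:::.model_eigen(model)
  rts <- ribosort:::.model_rates(model)
  po <- ape::reorder.phylo(tree, "postorder")
  nt <- length(tree$tip.label)
  sr <- sample(rts, n, replace = TRUE)
  seqs <- vector("list", nt + tree$Nnode)
  root <- po$edge[nrow(po$edge), 1]
  seqs[[root]] <- sample.int(4, n, replace = TRUE, prob = model$freqs)
  for (k in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    s <- seqs[[p]]
    out <- integer(n)
    for (r in unique(sr)) {
      P <- ribosort:::.pmat(eig, po$edge.length[k], r)
      idx <- which(sr == r)
      for (st in 1:4) {
        ii <- idx[s[idx] == st]
        if (length(ii)) out[ii] <- sample.int(4, length(ii), TRUE, prob = P[st, ])
      }
    }
    seqs[[ch]] <- out
  }
  m <- do.call(rbind, lapply(seq_len(nt),
                             function(i) c("A", "C", "G", "T")[seqs[[i]]]))
  rownames(m) <- tree$tip.label
  m
}

# brute-force likelihood: sum over every internal-node state assignment
exhaustive_lnl <- function(tree, m, model) {
  eig <- ribosort:::.model_eigen(model)
  rates <- ribosort:::.model_rates(model)
  nt <- length(tree$tip.label)
  code <- c(A = 1, C = 2, G = 3, T = 4)
  X <- matrix(code[m], nrow(m)); rownames(X) <- rownames(m)
  X <- X[tree$tip.label, , drop = FALSE]
  nn <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  root <- po$edge[nrow(po$edge), 1]
  ll <- 0
  for (s in seq_len(ncol(X))) {
    lik <- 0
    for (r in rates) {
      Ps <- lapply(seq_len(nrow(tree$edge)), function(k)
        ribosort:::.pmat(eig, tree$edge.length[k], r))
      grid <- as.matrix(expand.grid(rep(list(1:4), nn)))
      for (gi in seq_len(nrow(grid))) {
        st <- integer(nt + nn)
        st[seq_len(nt)] <- X[, s]
        st[(nt + 1):(nt + nn)] <- grid[gi, ]
        p <- model$freqs[st[root]]
        for (k in seq_len(nrow(tree$edge)))
          p <- p * Ps[[k]][st[tree$edge[k, 1]], st[tree$edge[k, 2]]]
        lik <- lik + p / length(rates)
      }
    }
    ll <- ll + log(lik)
  }
  ll
}

split_keys <- function(tree) sort(names(ribosort:::.tree_splits(tree)$internal))

.s2v_test <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
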