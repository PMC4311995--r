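#' @useDynLib ribosort, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize optim runif rexp rgamma rbinom rpois qgamma
#'   median mad sd integrate setNames
#' @importFrom utils combn read.table write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions do not disturb the session stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# ---- string helpers ---------------------------------------------------------

.s2v <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
.v2s <- function(v) paste(v, collapse = "")

.dna_code <- c(A = 1L, C = 2L, G = 3L, T = 4L, U = 4L)

# integer encode one sequence string: 1..4, NA for gap/N/ambiguity
.encode_seq <- function(s) {
  v <- .dna_code[.s2v(toupper(s))]
  unname(v)
}

# ---- split / clade machinery ------------------------------------------------

# tip sets for every node (index 1..Ntip+Nnode), postorder fill
.node_tipsets <- function(phy) {
  nt <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  sets <- vector("list", nt + phy$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- phy$tip.label[i]
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# canonical key of a bipartition side: the side NOT containing the
# alphabetically first tip, tips sorted and joined by "|"
.split_key <- function(side, all_tips) {
  ref <- min(all_tips)
  if (ref %in% side) side <- setdiff(all_tips, side)
  paste(sort(side), collapse = "|")
}

# all splits of a tree with branch lengths.
# Returns list(tips, internal = data.frame(key, length), pendant named numeric,
#              sides = list key -> tip vector)
.tree_splits <- function(phy) {
  if (ape::is.rooted(phy) && length(phy$tip.label) > 2L)
    phy <- ape::unroot(phy)
  nt <- length(phy$tip.label)
  all_tips <- phy$tip.label
  sets <- .node_tipsets(phy)
  el <- phy$edge.length %||% rep(NA_real_, nrow(phy$edge))
  pend <- setNames(rep(NA_real_, nt), all_tips)
  keys <- character(0); lens <- numeric(0); sides <- list()
  for (k in seq_len(nrow(phy$edge))) {
    ch <- phy$edge[k, 2]
    if (ch <= nt) {
      pend[phy$tip.label[ch]] <- el[k]
    } else {
      side <- sets[[ch]]
      if (length(side) <= 1L || length(side) >= nt - 1L) next
      key <- .split_key(side, all_tips)
      keys <- c(keys, key); lens <- c(lens, el[k])
      sides[[key]] <- sort(if (min(all_tips) %in% side)
        setdiff(all_tips, side) else side)
    }
  }
  list(tips = sort(all_tips),
       internal = setNames(lens, keys),
       pendant = pend, sides = sides)
}

# Inner Newick fragment (comma-joined children) for a tip set given a
# compatible clade list (tip vectors); shared by the tree builders below.
.newick_fragment <- function(set, clades, clade_len = NULL, clade_lab = NULL,
                             tip_len = NULL) {
  fmt <- function(x) sprintf("%.10g", x)
  tip_part <- function(tp) {
    l <- tip_len[[tp]] %||% NA_real_
    if (is.null(tip_len) || is.na(l)) tp else paste0(tp, ":", fmt(l))
  }
  if (length(clades)) {
    ord <- order(vapply(clades, length, 1L), decreasing = TRUE)
    clades <- clades[ord]
    if (!is.null(clade_len)) clade_len <- clade_len[ord]
    if (!is.null(clade_lab)) clade_lab <- clade_lab[ord]
  }
  build_set <- function(set, idx) {
    parts <- character(0)
    covered <- character(0)
    remaining <- idx
    while (length(remaining)) {
      i <- remaining[1]                       # largest remaining => maximal
      ci <- clades[[i]]
      inner <- remaining[vapply(remaining, function(j)
        j != i && all(clades[[j]] %in% ci), TRUE)]
      lab <- if (!is.null(clade_lab) && !is.na(clade_lab[i])) clade_lab[i] else ""
      len <- if (!is.null(clade_len) && !is.na(clade_len[i]))
        paste0(":", fmt(clade_len[i])) else ""
      parts <- c(parts, paste0("(", build_set(ci, inner), ")", lab, len))
      covered <- c(covered, ci)
      remaining <- remaining[!vapply(remaining, function(j)
        any(clades[[j]] %in% ci), TRUE)]
    }
    loose <- sort(setdiff(set, covered))
    parts <- c(parts, vapply(loose, tip_part, ""))
    paste(parts, collapse = ",")
  }
  build_set(sort(set), seq_along(clades))
}

# Build a tree from a compatible set of clades (tip vectors, none containing
# the reference tip), with branch lengths and optional clade labels.
.tree_from_clades <- function(all_tips, clades, clade_len = NULL,
                              clade_lab = NULL, tip_len = NULL) {
  txt <- paste0("(", .newick_fragment(all_tips, clades, clade_len, clade_lab,
                                      tip_len), ");")
  ape::read.tree(text = txt)
}

# Rebuild a phylo from a .tree_splits-style description
.tree_from_splits <- function(sp, clade_lab = NULL) {
  keys <- names(sp$internal)
  clades <- lapply(keys, function(k) sp$sides[[k]])
  .tree_from_clades(sp$tips, clades,
                    clade_len = unname(sp$internal),
                    clade_lab = if (is.null(clade_lab)) NULL else clade_lab[keys],
                    tip_len = as.list(sp$pendant))
}

#' All nearest-neighbour-interchange neighbours of an unrooted tree
#'
#' For every internal branch the two alternative arrangements of the four
#' adjacent subtrees are generated; branch lengths are carried over, the
#' rearranged branch inheriting the original branch's length.
#'
#' @param phy an (effectively unrooted) `phylo` with branch lengths.
#' @return A list of `phylo` objects (2 per internal branch).
#' @export
nni_neighbors <- function(phy) {
  if (ape::is.rooted(phy) && length(phy$tip.label) > 2L)
    phy <- ape::unroot(phy)
  sp <- .tree_splits(phy)
  nt <- length(phy$tip.label)
  sets <- .node_tipsets(phy)
  all_tips <- phy$tip.label
  root <- nt + 1L
  parent_of <- integer(nt + phy$Nnode)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  children <- function(n) phy$edge[phy$edge[, 1] == n, 2]
  out <- list()
  for (k in seq_len(nrow(phy$edge))) {
    u <- phy$edge[k, 1]; v <- phy$edge[k, 2]
    if (v <= nt) next                       # pendant edge
    key <- .split_key(sets[[v]], all_tips)
    if (!key %in% names(sp$internal)) next  # trivial
    chv <- children(v)
    if (length(chv) != 2L) next
    X <- list(sets[[chv[1]]], sets[[chv[2]]])
    # the other neighbours of u
    chu <- setdiff(children(u), v)
    Y <- lapply(chu, function(w) sets[[w]])
    if (u != root) Y <- c(Y, list(setdiff(all_tips, sets[[u]])))
    if (length(Y) != 2L) next
    for (yi in 1:2) {
      new_side <- sort(c(X[[2]], Y[[yi]]))
      sp2 <- sp
      ik <- which(names(sp2$internal) == key)
      nk <- .split_key(new_side, all_tips)
      names(sp2$internal)[ik] <- nk
      sp2$sides[[key]] <- NULL
      sp2$sides[[nk]] <- sort(if (min(all_tips) %in% new_side)
        setdiff(all_tips, new_side) else new_side)
      out[[length(out) + 1L]] <- .tree_from_splits(sp2)
    }
  }
  out
}

# one uniformly chosen NNI neighbour (random internal edge, random of the
# two arrangements); proposal is symmetric under this scheme
.nni_random <- function(phy) {
  if (ape::is.rooted(phy) && length(phy$tip.label) > 2L)
    phy <- ape::unroot(phy)
  sp <- .tree_splits(phy)
  nt <- length(phy$tip.label)
  sets <- .node_tipsets(phy)
  all_tips <- phy$tip.label
  root <- nt + 1L
  children <- function(n) phy$edge[phy$edge[, 1] == n, 2]
  cand <- which(phy$edge[, 2] > nt)
  cand <- cand[vapply(cand, function(k) {
    side <- sets[[phy$edge[k, 2]]]
    length(side) > 1L && length(side) < nt - 1L
  }, TRUE)]
  if (!length(cand)) return(phy)
  k <- cand[sample.int(length(cand), 1)]
  u <- phy$edge[k, 1]; v <- phy$edge[k, 2]
  key <- .split_key(sets[[v]], all_tips)
  chv <- children(v)
  if (length(chv) != 2L) return(phy)
  X <- list(sets[[chv[1]]], sets[[chv[2]]])
  chu <- setdiff(children(u), v)
  Y <- lapply(chu, function(w) sets[[w]])
  if (u != root) Y <- c(Y, list(setdiff(all_tips, sets[[u]])))
  if (length(Y) != 2L) return(phy)
  yi <- sample.int(2L, 1)
  new_side <- sort(c(X[[2]], Y[[yi]]))
  sp2 <- sp
  ik <- which(names(sp2$internal) == key)
  nk <- .split_key(new_side, all_tips)
  names(sp2$internal)[ik] <- nk
  sp2$sides[[key]] <- NULL
  sp2$sides[[nk]] <- sort(if (min(all_tips) %in% new_side)
    setdiff(all_tips, new_side) else new_side)
  .tree_from_splits(sp2)
}

# p-distance between two rows of a character matrix (gaps/N ignored)
.pdist <- function(a, b) {
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NA_real_)
  mean(a[ok] != b[ok])
}
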