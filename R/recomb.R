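# Sawyer-type (GENECONV-like) detection of gene-conversion / chimeric ITS
# copies.  For each sequence pair, the maximal-scoring run of agreement over
# informative columns is compared with a permutation null in which column
# order is shuffled identically for all rows.

#' Settings for recombination detection
#'
#' @param g mismatch penalty; the j-th mismatch inside a candidate fragment
#'   scores `-g * j` (quadratic ramp).  The default `Inf` admits no
#'   mismatches, so fragments are maximal identical runs — the classic
#'   inner-fragment convention; finite `g` is the documented relaxation
#'   for noisier data.
#' @param n_perm number of permutations (>= 99).
#' @param alpha significance level.
#' @param correction multiple-testing correction over pairs:
#'   `"bonferroni"` (GENECONV-like global) or `"bh"`.
#' @param seed RNG seed for the permutations.
#' @return A list of class `recomb_settings`.
#' @export
recomb_settings <- function(g = Inf, n_perm = 1000L, alpha = 0.05,
                            correction = c("bonferroni", "bh"), seed = 1L) {
  correction <- match.arg(correction)
  stopifnot(g >= 0, n_perm >= 99L, alpha > 0, alpha < 1)
  structure(list(g = g, n_perm = as.integer(n_perm), alpha = alpha,
                 correction = correction, seed = as.integer(seed)),
            class = "recomb_settings")
}

#' Polymorphic columns of an alignment
#'
#' @param aln a [ribo_alignment] (or character matrix).
#' @return 0-based, ascending column indices with >= 2 distinct non-gap,
#'   non-N states.
#' @export
polymorphic_sites <- function(aln) {
  m <- if (is.matrix(aln)) aln else as.matrix(aln)
  poly <- apply(m, 2, function(col) {
    u <- unique(col[col %in% c("A", "C", "G", "T")])
    length(u) >= 2L
  })
  which(poly) - 1L
}

# informative column set used for pairwise fragment scans: polymorphic
# columns for >2-row alignments; for a bare pair, all mutually comparable
# columns (a 2-row alignment's polymorphic columns are exactly its
# mismatches, which would degenerate the statistic).
.scan_sites <- function(m) {
  if (nrow(m) > 2L) polymorphic_sites(m)
  else {
    ok <- m[1, ] %in% c("A", "C", "G", "T") & m[2, ] %in% c("A", "C", "G", "T")
    which(ok) - 1L
  }
}

#' Maximal-scoring pair fragment (Sawyer inner fragment)
#'
#' Finds the contiguous segment of the pair's match/mismatch profile with
#' maximal score (+1 per match, the j-th mismatch scoring `-g*j`); exact
#' over all segments, ties broken leftmost then longest.
#'
#' @param x,y equal-length site strings (characters over informative
#'   columns), or `x` may be a logical/0-1 match vector with `y = NULL`.
#' @param g mismatch penalty ramp.
#' @return List with `score` (>= 0) and 0-based half-open `start`, `end`
#'   into the site list (`NULL` when no positive segment exists).
#' @export
best_fragment <- function(x, y = NULL, g = Inf) {
  if (is.null(y)) mv <- as.integer(x)
  else {
    a <- if (length(x) == 1L) .s2v(x) else x
    b <- if (length(y) == 1L) .s2v(y) else y
    stopifnot(length(a) == length(b))
    mv <- as.integer(a == b)
  }
  if (!length(mv)) return(list(score = 0, start = NULL, end = NULL))
  r <- .best_fragment_cpp(mv, g)
  if (r$start < 0) list(score = 0, start = NULL, end = NULL) else r
}

#' Permutation p-value for a pair's best fragment
#'
#' Columns of the informative site list are randomly reordered (identically
#' for both rows) `n_perm` times; `p = (1 + #{perm max score >= observed}) /
#' (n_perm + 1)`.
#'
#' @param aln a [ribo_alignment] (or character matrix).
#' @param pair character vector of two row ids (or indices).
#' @param observed_score observed best-fragment score; computed if `NULL`.
#' @param settings a [recomb_settings()].
#' @param max_exceed optional early-stopping exceedance count: once this
#'   many permutations reach the observed score the scan stops and the
#'   returned p-value is a conservative truncation (its comparison against
#'   `(max_exceed - 1) / (n_perm + 1)` is unaffected).  `NULL` = run all
#'   permutations.
#' @return p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(aln, pair, observed_score = NULL,
                               settings = recomb_settings(),
                               max_exceed = NULL) {
  m <- if (is.matrix(aln)) aln else as.matrix(aln)
  sites <- .scan_sites(m)
  a <- m[pair[1], sites + 1L]; b <- m[pair[2], sites + 1L]
  comparable <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  mv <- as.integer(a[comparable] == b[comparable])
  if (is.null(observed_score)) observed_score <- best_fragment(mv, g = settings$g)$score
  if (observed_score <= 0) return(1.0)
  with_seed(settings$seed, {
    r <- .perm_null_cpp(mv, settings$g, settings$n_perm, observed_score,
                        max_exceed = as.integer(max_exceed %||% 0))
    (1 + r[2]) / (r[1] + 1)
  })
}

#' Detect recombinant (chimeric) sequences
#'
#' All unordered pairs are scanned for a significant inner fragment
#' (permutation p-value, corrected over the number of pairs).  A member of
#' a significant pair is flagged recombinant when its nearest neighbour
#' inside the fragment differs from its nearest neighbour outside it (the
#' pair partner excluded from both searches) — the sharp-discontinuity
#' chimera criterion.
#'
#' @param aln a [ribo_alignment] of >= 3 sequences.
#' @param settings a [recomb_settings()].
#' @return List with `hits` (data frame: pair, fragment in full-alignment
#'   0-based half-open coordinates, score, `perm_p`, `corrected_p`,
#'   `significant`) and `recombinants` (character vector of flagged ids).
#' @export
detect_recombinants <- function(aln, settings = recomb_settings()) {
  m <- as.matrix(aln)
  stopifnot(nrow(m) >= 3L)
  ids <- rownames(m)
  sites <- .scan_sites(m)
  hits <- data.frame(idA = character(0), idB = character(0),
                     start = integer(0), end = integer(0),
                     score = numeric(0), perm_p = numeric(0))
  if (length(sites) == 0L)
    return(list(hits = cbind(hits, corrected_p = numeric(0),
                             significant = logical(0)),
                recombinants = character(0)))
  prs <- combn(ids, 2)
  np <- ncol(prs)
  if (settings$correction == "bonferroni" &&
      (settings$n_perm + 1) * settings$alpha < np)
    warning("n_perm too small for Bonferroni significance over ", np,
            " pairs; increase n_perm above ", ceiling(np / settings$alpha))
  # early stopping: a pair is hopeless once its p-value exceeds the most
  # permissive per-pair threshold the correction could require
  stop_at <- if (settings$correction == "bonferroni")
    ceiling(settings$alpha / np * (settings$n_perm + 1)) + 1L
  else ceiling(settings$alpha * (settings$n_perm + 1)) + 1L
  for (j in seq_len(np)) {
    a <- m[prs[1, j], sites + 1L]; b <- m[prs[2, j], sites + 1L]
    comparable <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    idx <- sites[comparable]
    mv <- as.integer(a[comparable] == b[comparable])
    bf <- best_fragment(mv, g = settings$g)
    if (bf$score <= 0) next
    pr_settings <- settings
    pr_settings$seed <- settings$seed + j       # independent streams per pair
    p <- permutation_pvalue(m, prs[, j], observed_score = bf$score,
                            settings = pr_settings, max_exceed = stop_at)
    hits <- rbind(hits, data.frame(
      idA = prs[1, j], idB = prs[2, j],
      start = idx[bf$start + 1L], end = idx[bf$end] + 1L,
      score = bf$score, perm_p = p))
  }
  if (!nrow(hits))
    return(list(hits = cbind(hits, corrected_p = numeric(0),
                             significant = logical(0)),
                recombinants = character(0)))
  hits$corrected_p <- if (settings$correction == "bonferroni")
    pmin(1, hits$perm_p * np) else p.adjust(hits$perm_p, "BH")
  hits$significant <- hits$corrected_p <= settings$alpha
  # chimera attribution: a pair member is recombinant when its nearest
  # neighbours on the two sides of the fragment disagree AND each side
  # matches its neighbour tightly (a chimera's flank matches its donor's
  # lineage closely; noisy neighbour flips do not).  Partner excluded from
  # the pool; a fragment touching an alignment end uses the fragment
  # interior as the missing side.  A second pass re-evaluates candidates
  # with all first-pass candidates removed from the neighbour pool, so
  # chimeras do not masquerade as neighbours of their own parents.
  attribute <- function(exclude_pool) {
    rec <- character(0)
    min_side <- 10L
    for (j in which(hits$significant)) {
      pairj <- c(hits$idA[j], hits$idB[j])
      inside <- seq(hits$start[j] + 1L, hits$end[j])
      left <- seq_len(hits$start[j])
      right <- if (hits$end[j] < ncol(m)) seq(hits$end[j] + 1L, ncol(m))
               else integer(0)
      sideA <- if (length(left) >= min_side) left else inside
      sideB <- if (length(right) >= min_side) right else inside
      if (identical(sideA, sideB)) next        # fragment spans everything
      for (s in pairj) {
        partner <- setdiff(pairj, s)
        others <- setdiff(ids, c(s, partner, exclude_pool))
        if (length(others) < 2L) next
        dists <- function(cols) vapply(others, function(o)
          .pdist(m[s, cols], m[o, cols]), 1)
        dA <- dists(sideA); dB <- dists(sideB)
        if (all(is.na(dA)) || all(is.na(dB))) next
        na <- others[which.min(dA)]; nb <- others[which.min(dB)]
        if (na == nb) next
        # crossing criterion: each flank's neighbour must beat the other
        # flank's neighbour clearly on its own flank
        margin <- 0.10
        if (!is.na(dA[nb]) && !is.na(dB[na]) &&
            dA[nb] - dA[na] >= margin && dB[na] - dB[nb] >= margin)
          rec <- c(rec, s)
      }
    }
    sort(unique(rec))
  }
  cand <- attribute(character(0))
  final <- intersect(cand, attribute(cand))
  list(hits = hits, recombinants = final)
}

#' @importFrom stats p.adjust
NULL
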