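# Functional-vs-pseudogene classification of cloned ITS paralogs.
#
# rDNA pseudogenes decay in characteristic ways: GC content drifts down
# (AT-biased mutation pressure no longer opposed by selection), the 5.8S
# secondary structure destabilises, the conserved seed-plant 14-bp 5.8S
# motif is lost, and the substitution rate increases.  Each criterion casts
# one vote; a sequence is called a pseudogene when enough criteria agree.

#' GC content of a sequence interval
#'
#' Fraction (G+C)/(A+C+G+T) over a 0-based half-open interval; gaps and N
#' are excluded from numerator and denominator.
#'
#' @param seq DNA string.
#' @param interval `c(start, end)`, 0-based half-open; `NULL` = whole string.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(seq, interval = NULL) {
  v <- .s2v(toupper(seq))
  if (!is.null(interval)) v <- v[(interval[1] + 1L):interval[2]]
  n <- sum(v %in% c("A", "C", "G", "T"))
  if (n == 0L) stop("interval contains no countable bases")
  sum(v %in% c("G", "C")) / n
}

#' Scan for a conserved motif allowing mismatches
#'
#' Finds the leftmost window minimising the Hamming distance to `motif`
#' (gap columns are deleted before scanning).
#'
#' @param seq DNA string (may contain gaps).
#' @param motif motif string.
#' @param max_mismatch maximum mismatches for `present = TRUE`.
#' @return List with `present`, `best_pos` (0-based, in the gap-free
#'   sequence; `NULL` if the sequence is shorter than the motif) and
#'   `mismatches`.
#' @export
motif_scan <- function(seq, motif = .MOTIF_5_8S, max_mismatch = 1L) {
  stopifnot(nchar(motif) >= 1L)
  v <- .s2v(toupper(seq)); v <- v[v != "-"]
  m <- .s2v(toupper(motif)); k <- length(m)
  if (length(v) < k)
    return(list(present = FALSE, best_pos = NULL, mismatches = NULL))
  nw <- length(v) - k + 1L
  mm <- integer(nw)
  for (j in seq_len(k)) mm <- mm + (v[j:(j + nw - 1L)] != m[j])
  best <- which.min(mm)                          # leftmost minimum
  list(present = mm[best] <= max_mismatch,
       best_pos = best - 1L, mismatches = mm[best])
}

#' Secondary-structure stability score (nested-structure minimum energy)
#'
#' Dynamic program over nested base-pairing structures: Watson-Crick pairs
#' score -1 (-2 when stacked directly on another pair), G:T wobble pairs
#' -0.5, hairpin loops of at least 3 unpaired bases.  Only relative
#' stability between paralogs is used by the classifier; the score is not a
#' thermodynamic nearest-neighbour free energy.
#'
#' @param seq gap-free DNA/RNA string of length >= 10.
#' @return A score `<= 0`; lower = more stable.
#' @export
fold_mfe <- function(seq) {
  v <- .s2v(toupper(seq))
  if (any(v == "-")) stop("fold_mfe requires a gap-free sequence")
  if (length(v) < 10L) stop("sequence too short to fold (< 10 nt)")
  if (mean(v == "N") > 0.2) stop("too ambiguous to fold (> 20% N)")
  codes <- .dna_code[v]
  codes[is.na(codes)] <- 0L
  .fold_mfe_cpp(as.integer(unname(codes)) - 1L, stack = -1, minloop = 3L)
}

#' Relative evolutionary rate of a focal sequence
#'
#' Mean p-distance from the focal sequence to each reference, divided by the
#' mean pairwise p-distance within the reference set.  Columns with a gap or
#' N in either row are ignored per comparison.
#'
#' @param aln a [ribo_alignment].
#' @param focal focal sequence id.
#' @param reference_set ids of at least 2 reference sequences (not
#'   containing `focal`).
#' @return A non-negative ratio; `Inf` (with a warning) when the references
#'   are identical to each other.
#' @export
relative_rate <- function(aln, focal, reference_set) {
  stopifnot(!(focal %in% reference_set), length(reference_set) >= 2L)
  m <- as.matrix(aln)
  f <- m[focal, ]
  d_f <- mean(vapply(reference_set, function(r) .pdist(f, m[r, ]), 1))
  prs <- combn(reference_set, 2)
  d_r <- mean(apply(prs, 2, function(p) .pdist(m[p[1], ], m[p[2], ])))
  if (d_r == 0) {
    if (d_f == 0) return(0)
    warning("reference sequences are identical; relative rate is infinite")
    return(Inf)
  }
  d_f / d_r
}

#' Classification thresholds
#'
#' @param gc_z_cut robust z-score cutoff for the low-GC vote.
#' @param motif_max_mismatch mismatches tolerated for the motif to count as
#'   present.
#' @param mfe_z_cut robust z-score cutoff for the unstable-5.8S vote.
#' @param rate_ratio_cut relative-rate ratio for the fast-evolution vote.
#' @param min_criteria votes needed to call a pseudogene.
#' @return A list of class `classify_thresholds`.
#' @export
classify_thresholds <- function(gc_z_cut = 2.0, motif_max_mismatch = 1L,
                                mfe_z_cut = 2.0, rate_ratio_cut = 2.0,
                                min_criteria = 2L) {
  stopifnot(gc_z_cut > 0, mfe_z_cut > 0, rate_ratio_cut > 0,
            min_criteria >= 1L, min_criteria <= 4L)
  structure(list(gc_z_cut = gc_z_cut, motif_max_mismatch = motif_max_mismatch,
                 mfe_z_cut = mfe_z_cut, rate_ratio_cut = rate_ratio_cut,
                 min_criteria = min_criteria), class = "classify_thresholds")
}

# robust z-scores against a baseline pool (median / MAD, with an sd fallback
# when the MAD degenerates)
.robust_z <- function(x, pool) {
  ctr <- median(pool)
  sc <- mad(pool)
  if (!is.finite(sc) || sc < 1e-9) sc <- sd(pool)
  if (!is.finite(sc) || sc < 1e-9) sc <- 1e-9
  (x - ctr) / sc
}

#' Compute per-paralog classification features
#'
#' @param aln a [ribo_alignment]; annotated with [annotate_alignment()] if
#'   no per-row regions are present.
#' @param anchors an [anchor_config()].
#' @return A data frame with one row per sequence: per-region GC, motif
#'   status, 5.8S fold score, lengths.
#' @export
paralog_features <- function(aln, anchors = anchor_config()) {
  if (is.null(aln$row_regions)) aln <- annotate_alignment(aln, anchors)
  n <- length(aln$ids)
  out <- data.frame(id = aln$ids, gc_its1 = NA_real_, gc_5_8s = NA_real_,
                    gc_its2 = NA_real_, gc_total = NA_real_,
                    motif_present = NA, motif_mismatches = NA_integer_,
                    mfe_5_8s = NA_real_, length_its1 = NA_integer_,
                    length_5_8s = NA_integer_, length_its2 = NA_integer_,
                    anchored = NA, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- aln$seqs[i]; rr <- aln$row_regions[[i]]
    sub <- function(iv) substr(s, iv[1] + 1L, iv[2])
    dg <- function(x) gsub("-", "", x, fixed = TRUE)
    s58 <- dg(sub(rr$r5_8s))
    out$gc_its1[i] <- gc_content(sub(rr$its1))
    out$gc_5_8s[i] <- gc_content(s58)
    out$gc_its2[i] <- gc_content(sub(rr$its2))
    out$gc_total[i] <- gc_content(dg(s))
    ms <- motif_scan(s58, anchors$motif, max_mismatch = anchors$max_mismatch)
    out$motif_mismatches[i] <- ms$mismatches %||% nchar(anchors$motif)
    out$motif_present[i] <- isTRUE(ms$present)
    out$mfe_5_8s[i] <- fold_mfe(s58)
    out$length_its1[i] <- nchar(dg(sub(rr$its1)))
    out$length_5_8s[i] <- nchar(s58)
    out$length_its2[i] <- nchar(dg(sub(rr$its2)))
    out$anchored[i] <- rr$anchored
  }
  out
}

#' Classify ITS paralogs as functional or pseudogene
#'
#' Two passes: (1) a provisional functional pool is formed from sequences
#' carrying the 5.8S motif within the mismatch budget; (2) each sequence
#' collects votes for the pseudogene label — GC robustly below the pool
#' (z <= -gc_z_cut), motif absent, 5.8S fold score robustly above the pool
#' (z >= mfe_z_cut, i.e. less stable), and relative rate >= rate_ratio_cut
#' against the pool.  A sequence is a pseudogene when votes >= min_criteria.
#' Recombinant labels are overlaid afterwards by [detect_recombinants()].
#'
#' @param aln a [ribo_alignment] of at least 4 sequences.
#' @param thresholds a [classify_thresholds()].
#' @param anchors an [anchor_config()].
#' @return A data frame (one row per sequence, input order) with features,
#'   per-criterion votes and the final `label`.
#' @export
classify_paralogs <- function(aln, thresholds = classify_thresholds(),
                              anchors = anchor_config()) {
  stopifnot(length(aln$ids) >= 4L)
  th <- thresholds
  fx <- paralog_features(aln, anchors)
  # deterministic under row permutation: order features by id for the pool
  pool_ids <- fx$id[fx$motif_present &
                    fx$motif_mismatches <= th$motif_max_mismatch]
  if (length(pool_ids) < 3L)
    stop("no functional baseline: provisional pool has fewer than 3 sequences")
  pool <- fx[match(sort(pool_ids), fx$id), ]
  fx$z_gc <- .robust_z(fx$gc_total, pool$gc_total)
  fx$z_mfe <- .robust_z(fx$mfe_5_8s, pool$mfe_5_8s)
  fx$rel_rate <- vapply(seq_len(nrow(fx)), function(i) {
    refs <- setdiff(sort(pool_ids), fx$id[i])
    if (length(refs) < 2L) return(NA_real_)
    suppressWarnings(relative_rate(aln, fx$id[i], refs))
  }, 1)
  fx$vote_gc <- fx$z_gc <= -th$gc_z_cut
  fx$vote_motif <- !fx$motif_present
  fx$vote_mfe <- fx$z_mfe >= th$mfe_z_cut
  fx$vote_rate <- !is.na(fx$rel_rate) & fx$rel_rate >= th$rate_ratio_cut
  fx$votes <- fx$vote_gc + fx$vote_motif + fx$vote_mfe + fx$vote_rate
  fx$label <- ifelse(fx$votes >= th$min_criteria, "pseudogene", "functional")
  class(fx) <- c("paralog_calls", "data.frame")
  fx
}

#' Write an S2-style feature/label report
#'
#' @param calls result of [classify_paralogs()].
#' @param path TSV output path.
#' @return Invisibly, `path`.
#' @export
write_classification <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
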