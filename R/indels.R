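# Simple indel coding (SIC): alignment gaps become binary
# presence/absence characters.  An indel event is a distinct non-terminal
# (start, end) gap span; a row scores 1 for an exactly matching gap run,
# 0 when it has residues across the event, and "?" (inapplicable) when one
# of its gap runs strictly contains the event.

# all maximal gap runs of one row: data.frame(start, end), 0-based half-open
.gap_runs <- function(v) {
  r <- rle(v == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Extract indel events from an alignment
#'
#' Every maximal internal gap run contributes a candidate event; identical
#' `(start, end)` spans merge.  Runs touching either alignment end are
#' treated as missing data, not indels.
#'
#' @param aln a [ribo_alignment] (or character matrix).
#' @return Data frame of events with 0-based half-open `start`, `end`,
#'   sorted by `(start, end)`.
#' @export
extract_indels <- function(aln) {
  m <- if (is.matrix(aln)) aln else as.matrix(aln)
  L <- ncol(m)
  ev <- unique(do.call(rbind, lapply(seq_len(nrow(m)), function(i)
    .gap_runs(m[i, ]))))
  if (is.null(ev) || !nrow(ev))
    return(data.frame(start = integer(0), end = integer(0)))
  ev <- ev[ev$start > 0L & ev$end < L, , drop = FALSE]   # terminal-gap rule
  ev <- ev[order(ev$start, ev$end), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Simple indel coding of an alignment
#'
#' @param aln a [ribo_alignment] (or character matrix).
#' @return A list of class `sic_matrix`: `ids`, `events` (as
#'   [extract_indels()]), `states` (character matrix over `"0"`, `"1"`,
#'   `"?"`, rows = ids) and `constant` (logical per event: no 0-scoring
#'   row; such characters are dropped by variable-coding likelihoods).
#' @export
sic_code <- function(aln) {
  m <- if (is.matrix(aln)) aln else as.matrix(aln)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  ev <- extract_indels(m)
  st <- matrix("0", nrow(m), nrow(ev), dimnames = list(ids, NULL))
  if (nrow(ev)) {
    runs <- lapply(seq_len(nrow(m)), function(i) .gap_runs(m[i, ]))
    for (i in seq_len(nrow(m))) {
      ri <- runs[[i]]
      if (!nrow(ri)) next
      for (e in seq_len(nrow(ev))) {
        s <- ev$start[e]; en <- ev$end[e]
        exact <- any(ri$start == s & ri$end == en)
        contains <- any(ri$start <= s & ri$end >= en &
                        !(ri$start == s & ri$end == en))
        st[i, e] <- if (exact) "1" else if (contains) "?" else "0"
      }
    }
  }
  constant <- if (nrow(ev)) apply(st, 2, function(col) !any(col == "0"))
              else logical(0)
  structure(list(ids = ids, events = ev, states = st, constant = constant),
            class = "sic_matrix")
}

#' @export
print.sic_matrix <- function(x, ...) {
  cat("sic_matrix:", length(x$ids), "rows x", nrow(x$events), "indel characters",
      if (any(x$constant)) paste0("(", sum(x$constant), " constant)"), "\n")
  invisible(x)
}

#' Write a SIC matrix as TSV
#'
#' @param sic a [sic_code()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_sic <- function(sic, path) {
  df <- data.frame(id = sic$ids, apply(sic$states, 1, paste, collapse = ""))
  names(df)[2] <- "indel_characters"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
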