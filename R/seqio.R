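# Sequence containers and external formats.
#
# Unaligned records are a named character vector of IUPAC DNA strings
# (names = unique ids).  Aligned data are a `ribo_alignment`: a list with
# $ids, $seqs (equal-length gapped strings), $length and an optional
# $region_map (ITS1 / 5.8S / ITS2 intervals in alignment coordinates).
# All coordinates are 0-based half-open.

.VALID_CHARS <- c("A", "C", "G", "T", "N", "-")

.check_records <- function(ids, seqs) {
  if (length(ids) == 0L) stop("no records")
  if (anyDuplicated(ids)) stop("duplicate ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(ids))) stop("empty id")
  bad <- vapply(seqs, function(s)
    any(!.s2v(toupper(s)) %in% .VALID_CHARS), TRUE)
  if (any(bad)) stop("invalid characters in: ", paste(ids[bad], collapse = ", "))
  invisible(TRUE)
}

#' Construct an alignment object
#'
#' @param ids character vector of unique sequence ids.
#' @param seqs character vector of equal-length gapped sequence strings
#'   (alphabet `A C G T N -`).
#' @param region_map optional list with elements `its1`, `r5_8s`, `its2`,
#'   each a 0-based half-open `c(start, end)` interval in alignment columns.
#' @return An object of class `ribo_alignment`.
#' @export
ribo_alignment <- function(ids, seqs, region_map = NULL) {
  seqs <- toupper(as.character(seqs))
  .check_records(ids, seqs)
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("ragged rows: aligned sequences must have equal length")
  structure(list(ids = as.character(ids), seqs = unname(seqs),
                 length = L, region_map = region_map),
            class = "ribo_alignment")
}

#' @export
print.ribo_alignment <- function(x, ...) {
  cat("ribo_alignment:", length(x$ids), "sequences x", x$length, "columns\n")
  if (!is.null(x$region_map))
    cat("  regions: ITS1 [", x$region_map$its1[1], ",", x$region_map$its1[2],
        ") 5.8S [", x$region_map$r5_8s[1], ",", x$region_map$r5_8s[2],
        ") ITS2 [", x$region_map$its2[1], ",", x$region_map$its2[2], ")\n")
  invisible(x)
}

#' @export
as.matrix.ribo_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seqs, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

# matrix -> alignment
.aln_from_matrix <- function(m) {
  ribo_alignment(rownames(m), apply(m, 1, paste, collapse = ""))
}

#' Read sequence records
#'
#' Reads FASTA, relaxed PHYLIP (whitespace-delimited names up to 64
#' characters) or NEXUS DATA blocks.  If all sequences have equal length and
#' `aligned = TRUE` (or the format implies alignment) a [ribo_alignment] is
#' returned, otherwise a named character vector.
#'
#' @param path file path.
#' @param format one of `"fasta"`, `"phylip_relaxed"`, `"nexus"`.
#' @param aligned return a [ribo_alignment]? Default: `TRUE` for PHYLIP and
#'   NEXUS, else `FALSE`.
#' @return Named character vector of sequences, or a [ribo_alignment].
#' @export
read_records <- function(path, format = c("fasta", "phylip_relaxed", "nexus"),
                         aligned = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  res <- switch(format,
    fasta = .read_fasta(lines),
    phylip_relaxed = .read_phylip(lines),
    nexus = .read_nexus(lines))
  .check_records(names(res), res)
  if (is.null(aligned)) aligned <- format != "fasta"
  if (aligned || format != "fasta") {
    if (length(unique(nchar(res))) != 1L)
      stop("ragged rows: sequences differ in length")
    return(ribo_alignment(names(res), res))
  }
  res
}

.read_fasta <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no records")
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("parse error at line 1: expected '>' header")
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) gsub("\\s", "", paste(x, collapse = "")), "")
  if (length(seqs) != length(ids)) stop("record with no sequence lines")
  setNames(toupper(unname(seqs)), ids)
}

.read_phylip <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no records")
  hd <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hd) < 2L || anyNA(suppressWarnings(as.integer(hd[1:2]))))
    stop("parse error at line 1: expected '<ntaxa> <nchar>' header")
  n <- as.integer(hd[1]); L <- as.integer(hd[2])
  if (length(lines) < n + 1L) stop("parse error: fewer rows than declared")
  ids <- character(n); seqs <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(f) < 2L) stop("parse error at line ", i + 1L)
    ids[i] <- f[1]
    seqs[i] <- gsub("\\s", "", paste(f[-1], collapse = ""))
    if (nchar(seqs[i]) != L)
      stop("parse error at line ", i + 1L, ": row length ", nchar(seqs[i]),
           " != declared ", L)
  }
  setNames(toupper(seqs), ids)
}

.read_nexus <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  m <- regmatches(txt, regexpr("(?is)matrix(.*?);", txt, perl = TRUE))
  if (!length(m)) stop("parse error: no MATRIX block")
  body <- sub("(?is)^matrix", "", m, perl = TRUE)
  body <- sub(";$", "", body)
  rows <- strsplit(body, "\n")[[1]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows) & !grepl("^\\[", rows)]
  ids <- character(0); seqs <- character(0)
  for (r in rows) {
    f <- strsplit(r, "\\s+")[[1]]
    if (length(f) < 2L) stop("parse error in MATRIX row: ", r)
    id <- gsub("^'|'$", "", f[1])
    s <- paste(f[-1], collapse = "")
    i <- match(id, ids)
    if (is.na(i)) { ids <- c(ids, id); seqs <- c(seqs, s) }
    else seqs[i] <- paste0(seqs[i], s)     # interleaved continuation
  }
  if (!length(ids)) stop("no records")
  # MIXED(DNA:1-N, RESTRICTION:...) matrices: return the DNA partition
  fm <- regmatches(txt, regexpr("(?i)MIXED\\(DNA:1-([0-9]+)", txt, perl = TRUE))
  if (length(fm)) {
    L <- as.integer(sub("(?i)MIXED\\(DNA:1-", "", fm, perl = TRUE))
    seqs <- substr(seqs, 1L, L)
  }
  setNames(toupper(seqs), ids)
}

#' Write sequence records
#'
#' @param x named character vector of sequences or a [ribo_alignment].
#' @param path output path.
#' @param format `"fasta"`, `"phylip_relaxed"` or `"nexus"`.
#' @param indels optional [sic_code()] binary matrix; when given with
#'   `format = "nexus"`, a second (restriction/binary) partition is written
#'   and both charsets declared in an ASSUMPTIONS block.
#' @param strip_gaps drop `-` characters before writing (unaligned FASTA
#'   export of aligned rows).
#' @return Invisibly, `path`.
#' @export
write_records <- function(x, path, format = c("fasta", "phylip_relaxed", "nexus"),
                          indels = NULL, strip_gaps = FALSE) {
  format <- match.arg(format)
  if (inherits(x, "ribo_alignment")) { ids <- x$ids; seqs <- x$seqs }
  else { ids <- names(x); seqs <- unname(x) }
  if (strip_gaps) seqs <- gsub("-", "", seqs, fixed = TRUE)
  if (format != "fasta" && length(unique(nchar(seqs))) != 1L)
    stop("ragged rows: aligned output format requires equal lengths")
  lines <- switch(format,
    fasta = as.vector(rbind(paste0(">", ids), seqs)),
    phylip_relaxed = c(paste(length(ids), nchar(seqs[1])),
                       paste(ids, seqs)),
    nexus = .nexus_lines(ids, seqs, indels))
  writeLines(lines, path)
  invisible(path)
}

.nexus_lines <- function(ids, seqs, indels = NULL) {
  L <- nchar(seqs[1])
  qid <- ifelse(grepl("[^A-Za-z0-9_.]", ids), paste0("'", ids, "'"), ids)
  nbin <- 0L
  if (!is.null(indels)) {
    bm <- indels$states[match(ids, indels$ids), , drop = FALSE]
    nbin <- ncol(bm)
    seqs_out <- paste0(seqs, apply(bm, 1, paste, collapse = ""))
  } else seqs_out <- seqs
  out <- c("#NEXUS", "BEGIN DATA;",
           sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(ids), L + nbin),
           if (nbin > 0)
             sprintf("  FORMAT DATATYPE=MIXED(DNA:1-%d,RESTRICTION:%d-%d) GAP=- MISSING=?;",
                     L, L + 1L, L + nbin)
           else "  FORMAT DATATYPE=DNA GAP=- MISSING=?;",
           "  MATRIX",
           paste0("    ", format(qid, width = max(nchar(qid)) + 2L), seqs_out),
           "  ;", "END;")
  if (nbin > 0)
    out <- c(out, "BEGIN ASSUMPTIONS;",
             sprintf("  CHARSET dna = 1-%d;", L),
             sprintf("  CHARSET indels = %d-%d;", L + 1L, L + nbin),
             "END;")
  out
}

#' Read / write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that record
#' how node support labels are scaled.
#'
#' @param path file path.
#' @param support_scale `"bpp"` (supports in `[0,1]`) or `"bootstrap"`
#'   (`[0,100]`); stored as an attribute, not used numerically here.
#' @return A `phylo` (read) or, invisibly, `path` (write).
#' @export
read_newick <- function(path, support_scale = c("bpp", "bootstrap")) {
  support_scale <- match.arg(support_scale)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("parse error: not a valid Newick file")
  attr(tr, "support_scale") <- support_scale
  tr
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# ---- region annotation ------------------------------------------------------

# A synthetic 160-nt 5.8S reference carrying the conserved seed-plant
# 14-bp motif GAATTGCAGAATCC at offset 41 (0-based).  Used as the default
# anchor for locating the 5.8S gene inside a cloned ITS sequence; it is a
# constructed stand-in with realistic base composition, not a database entry.
.REF_5_8S <- paste0(
  "CGACTCTCGGCAACGGATATCTCGGCTCTCGCATCGATGAA",   # 0..40
  "GAATTGCAGAATCC",                               # 41..54 motif
  "CGTGAACCATCGAGTCTTTGAACGCAAGTTGCGCCCGAGGCCATCCGGCTGAGGGCACGC",
  "CTGCCTGGGCGTCACGCATCGCGTCGCCCCCACCACACCTCACGG")

.MOTIF_5_8S <- "GAATTGCAGAATCC"

#' Default anchoring configuration for ITS region annotation
#'
#' The 5.8S gene is located by the best hit (minimum Hamming distance,
#' leftmost tie-break) of the 14-bp conserved motif within a sequence; the
#' 5.8S interval is then laid out around the hit using the motif's offset in
#' a reference 5.8S. Sequences without a hit within `max_mismatch` keep
#' proportional fallback regions and are flagged unanchored.
#'
#' @param reference reference 5.8S sequence (synthetic stand-in by default).
#' @param motif the conserved 5.8S motif.
#' @param motif_offset 0-based offset of the motif within `reference`.
#' @param max_mismatch maximum Hamming mismatches for an anchor hit.
#' @param min_len minimum sequence length to attempt annotation.
#' @param fallback proportional `(ITS1, 5.8S, ITS2)` fractions used when
#'   unanchored.
#' @return A list of class `anchor_config`.
#' @export
anchor_config <- function(reference = .REF_5_8S, motif = .MOTIF_5_8S,
                          motif_offset = 41L, max_mismatch = 2L,
                          min_len = 300L, fallback = c(0.40, 0.15, 0.45)) {
  structure(list(reference = reference, motif = motif,
                 motif_offset = as.integer(motif_offset),
                 max_mismatch = as.integer(max_mismatch),
                 min_len = as.integer(min_len), fallback = fallback),
            class = "anchor_config")
}

#' Annotate ITS1 / 5.8S / ITS2 regions within one sequence
#'
#' @param seq a DNA string (gaps allowed; coordinates refer to the input
#'   string, gap columns included).
#' @param anchors an [anchor_config()].
#' @return A list with 0-based half-open intervals `its1`, `r5_8s`, `its2`
#'   and a logical `anchored`.
#' @export
annotate_regions <- function(seq, anchors = anchor_config()) {
  L <- nchar(seq)
  if (L < anchors$min_len)
    stop("sequence shorter than configured minimum (", anchors$min_len, ")")
  v <- .s2v(toupper(seq))
  keep <- v != "-"
  dg <- v[keep]
  map <- which(keep)                     # degapped index -> original column
  hit <- motif_scan(.v2s(dg), anchors$motif, anchors$max_mismatch)
  ref_len <- nchar(anchors$reference)
  ok <- hit$present
  if (ok) {
    s58 <- hit$best_pos - anchors$motif_offset        # 0-based, degapped
    e58 <- s58 + ref_len
    if (s58 <= 0L || e58 >= length(dg)) ok <- FALSE   # empty ITS1/ITS2
  }
  if (!ok) {
    f <- cumsum(anchors$fallback) / sum(anchors$fallback)
    n <- length(dg)
    b1 <- max(1L, round(n * f[1])); b2 <- max(b1 + 1L, round(n * f[2]))
    its1 <- c(0L, b1); r58 <- c(b1, b2); its2 <- c(b2, n)
  } else {
    its1 <- c(0L, s58); r58 <- c(s58, e58); its2 <- c(e58, length(dg))
  }
  # map degapped coordinates back to original string columns
  back <- function(iv) c(map[iv[1] + 1L] - 1L,
                         if (iv[2] >= length(dg)) max(map) else map[iv[2] + 1L] - 1L)
  list(its1 = back(its1), r5_8s = back(r58), its2 = back(its2),
       anchored = ok)
}

#' Annotate an alignment's region map
#'
#' Annotates every row, then takes the median boundary over anchored rows
#' (falling back to proportional regions when no row anchors).
#'
#' @param aln a [ribo_alignment].
#' @param anchors an [anchor_config()].
#' @return The alignment with `$region_map` set (plus per-row annotations in
#'   `$row_regions`).
#' @export
annotate_alignment <- function(aln, anchors = anchor_config()) {
  ann <- lapply(aln$seqs, annotate_regions, anchors = anchors)
  names(ann) <- aln$ids
  anch <- vapply(ann, `[[`, TRUE, "anchored")
  use <- if (any(anch)) ann[anch] else ann
  b1 <- round(median(vapply(use, function(a) a$r5_8s[1], 1)))
  b2 <- round(median(vapply(use, function(a) a$r5_8s[2], 1)))
  aln$region_map <- list(its1 = c(0L, b1), r5_8s = c(b1, b2),
                         its2 = c(b2, aln$length))
  aln$row_regions <- ann
  aln
}
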