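# End-to-end study workflow: classify paralogs, screen recombination,
# build the all-paralog unrooted ML tree (recombinants excluded), run the
# Bayesian analysis on functional copies plus selected pseudogene
# outgroups with the SIC binary partition, root on the pseudogenes, and
# reconstruct ancestral areas on the pseudogene-free tree sample.

#' Pipeline configuration
#'
#' @param alignment a [ribo_alignment] (or FASTA path read with
#'   [read_records()]).
#' @param areas area table (path or data frame) for [code_areas()], mapping
#'   species tags to area letters; sequence ids are mapped to species by
#'   stripping the trailing `_<clone>` suffix.
#' @param thresholds a [classify_thresholds()].
#' @param recomb a [recomb_settings()].
#' @param mcmc an [mcmc_settings()].
#' @param bbm a [bbm_settings()].
#' @param model DNA [subst_model()]; `NULL` = select by AIC.
#' @param bin_model [binary_model()] for the indel partition.
#' @param outgroup_policy `"all_pseudogenes"` or `"listed_ids"`.
#' @param outgroup_ids pseudogene ids used when `outgroup_policy =
#'   "listed_ids"`.
#' @param out_dir optional directory for artifacts (TSV/Newick/NEXUS).
#' @param seed master seed; all stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(alignment, areas = NULL,
                       thresholds = classify_thresholds(),
                       recomb = recomb_settings(),
                       mcmc = mcmc_settings(),
                       bbm = bbm_settings(),
                       model = NULL, bin_model = binary_model(),
                       outgroup_policy = c("all_pseudogenes", "listed_ids"),
                       outgroup_ids = NULL, out_dir = NULL, seed = 1L) {
  outgroup_policy <- match.arg(outgroup_policy)
  structure(list(alignment = alignment, areas = areas,
                 thresholds = thresholds, recomb = recomb, mcmc = mcmc,
                 bbm = bbm, model = model, bin_model = bin_model,
                 outgroup_policy = outgroup_policy,
                 outgroup_ids = outgroup_ids, out_dir = out_dir,
                 seed = as.integer(seed)), class = "run_config")
}

.species_of <- function(ids) sub("_[^_]*$", "", ids)

#' Run the full analysis pipeline
#'
#' Stages: (1) classification; (2) recombination screening on all paralogs,
#' recombinant labels overlaid (recombinants are counted on the pseudogene
#' side, mirroring the convention that chimeras are non-functional); (3)
#' all-paralog unrooted ML tree excluding recombinants; (4) SIC coding and
#' Bayesian MCMC (2 runs) on functional copies + outgroup pseudogenes,
#' ASDSF convergence check, majority-rule consensus; (5) rooting on the
#' pseudogene outgroup; (6) BBM ancestral areas on the pseudogene-free
#' posterior tree sample.  All randomness derives from `config$seed`.
#'
#' @param config a [run_config()].
#' @return A list of class `run_report` with per-stage results and a counts
#'   table (`total`, `functional`, `pseudogene_side`, `recombinant`, plus a
#'   printed consistency line; discrepancies are reported, never
#'   reconciled).
#' @export
run_all <- function(config) {
  cf <- config
  aln <- if (is.character(cf$alignment))
    read_records(cf$alignment, "fasta", aligned = TRUE) else cf$alignment
  stage <- "classify"
  report <- list(seed = cf$seed, stages = character(0))
  tryCatch({
    calls <- classify_paralogs(aln, cf$thresholds)
    report$classification <- calls
    report$stages <- c(report$stages, stage)

    stage <- "recomb"
    rs <- cf$recomb; rs$seed <- cf$seed + 17L
    rec <- detect_recombinants(aln, rs)
    report$recomb <- rec
    calls$label[calls$id %in% rec$recombinants] <- "recombinant"
    report$calls <- calls
    n_total <- nrow(calls)
    n_rec <- sum(calls$label == "recombinant")
    n_pseudo_side <- sum(calls$label == "pseudogene") + n_rec
    n_func <- sum(calls$label == "functional")
    counts <- data.frame(total = n_total, functional = n_func,
                         pseudogene_side = n_pseudo_side,
                         recombinant = n_rec)
    counts$consistency <- sprintf(
      "functional + pseudogene_side = %d vs total = %d (difference %d)",
      n_func + n_pseudo_side, n_total, n_total - (n_func + n_pseudo_side))
    report$counts <- counts
    report$stages <- c(report$stages, stage)

    stage <- "all_paralog_ml"
    keep <- calls$id[calls$label != "recombinant"]
    sub_aln <- function(ids) {
      m <- as.matrix(aln)[ids, , drop = FALSE]
      a <- .aln_from_matrix(m); a$region_map <- aln$region_map; a
    }
    aln_np <- sub_aln(keep)
    model <- cf$model %||% model_select_aic(aln_np)$best
    report$model <- model
    fit_all <- ml_search(aln_np, model)
    report$all_paralog_tree <- fit_all$tree
    report$all_paralog_lnL <- fit_all$lnL
    func_ids <- calls$id[calls$label == "functional"]
    pseudo_ids <- calls$id[calls$label == "pseudogene"]
    report$reciprocal_monophyly <-
      check_reciprocal_monophyly(fit_all$tree, func_ids,
                                 setdiff(keep, func_ids))
    report$stages <- c(report$stages, stage)

    stage <- "bayes"
    og <- if (cf$outgroup_policy == "listed_ids") {
      stopifnot(all(cf$outgroup_ids %in% pseudo_ids))
      cf$outgroup_ids
    } else pseudo_ids
    aln_fun <- sub_aln(c(func_ids, og))
    sic <- sic_code(aln_fun)
    has_var_bin <- nrow(sic$events) > 0 && any(!sic$constant)
    ms <- cf$mcmc; ms$seed <- cf$seed + 29L
    runs <- mcmc_run(aln_fun, model,
                     sic = if (has_var_bin) sic else NULL,
                     bin_model = cf$bin_model, settings = ms, n_runs = 2L)
    report$asdsf <- asdsf(runs[[1]], runs[[2]], ms$burnin_frac)
    cons <- majority_consensus(runs, ms$burnin_frac)
    report$consensus <- cons
    report$stages <- c(report$stages, stage)

    stage <- "rooting"
    rooted <- tryCatch(root_on_clade(cons, og), error = function(e) e)
    report$rooted <- rooted
    report$rooting_ok <- inherits(rooted, "phylo")
    report$stages <- c(report$stages, stage)

    stage <- "biogeo"
    if (!is.null(cf$areas)) {
      post <- .post_burnin(runs[[1]], ms$burnin_frac)
      sp_map <- .species_of(func_ids)
      area_df <- if (is.character(cf$areas))
        read.table(cf$areas, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE) else as.data.frame(cf$areas)
      # expand species-level areas to clone ids
      area_seq <- data.frame(taxon = func_ids,
                             areas = area_df$areas[match(sp_map, area_df$taxon)],
                             stringsAsFactors = FALSE)
      if (anyNA(area_seq$areas))
        stop("missing area coding for: ",
             paste(func_ids[is.na(area_seq$areas)], collapse = ", "))
      am <- code_areas(area_seq, taxa = func_ids)
      # each posterior tree is rooted on a single outgroup clone (the
      # outgroup need not be monophyletic in every sampled topology), then
      # the outgroup tips are removed
      pruned <- lapply(post, function(tr) {
        r <- ape::root(tr, outgroup = og[1], resolve.root = TRUE)
        ape::drop.tip(r, og)
      })
      bs <- cf$bbm; bs$seed <- cf$seed + 43L
      report$bbm <- bbm_ancestral(pruned, am, bs)
      report$ranges <- summarize_ranges(report$bbm)
      report$stages <- c(report$stages, stage)
    }
    class(report) <- "run_report"
    if (!is.null(cf$out_dir)) .write_artifacts(report, aln_fun, sic, cf)
    report
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

.write_artifacts <- function(report, aln_fun, sic, cf) {
  d <- cf$out_dir
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  write_classification(report$calls, file.path(d, "classification.tsv"))
  write.table(report$recomb$hits, file.path(d, "recomb_hits.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(report$counts, file.path(d, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_newick(report$all_paralog_tree, file.path(d, "all_paralogs_ml.nwk"))
  write_newick(report$consensus, file.path(d, "consensus.nwk"))
  if (report$rooting_ok)
    write_newick(report$rooted, file.path(d, "rooted.nwk"))
  write_records(aln_fun, file.path(d, "functional_matrix.nex"),
                format = "nexus", indels = sic)
  if (!is.null(report$ranges))
    write.table(report$ranges, file.path(d, "ancestral_ranges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(sprintf("seed\t%d", report$seed),
               sprintf("asdsf\t%.6f", report$asdsf %||% NA),
               sprintf("stages\t%s", paste(report$stages, collapse = ","))),
             file.path(d, "run_log.tsv"))
  invisible(d)
}

#' @export
print.run_report <- function(x, ...) {
  cat("ribosort run (seed", x$seed, ")\n")
  cat("stages completed:", paste(x$stages, collapse = " -> "), "\n")
  if (!is.null(x$counts)) {
    cat(sprintf("counts: total %d | functional %d | pseudogene-side %d (of which %d recombinant)\n",
                x$counts$total, x$counts$functional, x$counts$pseudogene_side,
                x$counts$recombinant))
    cat(" ", x$counts$consistency, "\n")
  }
  if (!is.null(x$asdsf)) cat(sprintf("ASDSF between runs: %.4f\n", x$asdsf))
  if (!is.null(x$reciprocal_monophyly))
    cat("functional/pseudogene reciprocal monophyly:", x$reciprocal_monophyly, "\n")
  invisible(x)
}
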