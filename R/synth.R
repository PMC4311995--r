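# Seeded simulator for ITS paralog families with known truth.  A paralog
# gene tree is grafted onto a pure-birth-style species tree: one functional
# subtree (clones per species under purifying constraint: slow 5.8S, stable
# GC, intact 14-bp motif) and one mirrored pseudogene subtree (rate
# multiplier, AT-shifted equilibrium, motif knockout, extra indels),
# joined at the root so functional and pseudogene copies are reciprocally
# monophyletic by construction.  Recombinants are spliced post hoc from two
# parent sequences at a drawn breakpoint.  The emitted alignment is the
# true simulated homology (deletions only), so no aligner is involved.

#' Simulation configuration
#'
#' Defaults are the package's study conditions: stated pseudogene effect
#' sizes (rate x3, GC equilibrium shift -0.12, motif knockout probability
#' 0.9, indel rate x4) on a desk-scale family of 8 species with 2
#' functional + 1 pseudogene clone each and 2 recombinants.
#'
#' @param n_species number of species.
#' @param n_functional,n_pseudogene clones per species.
#' @param seq_lengths named lengths `(its1, r5_8s, its2)` in nt.
#' @param model base [subst_model()] for functional evolution.
#' @param tree_depth species-tree depth in expected substitutions/site.
#' @param clone_depth within-species clone divergence.
#' @param rate_multiplier pseudogene branch-rate multiplier.
#' @param gc_shift shift of equilibrium GC content in pseudogenes
#'   (negative = toward A/T).
#' @param motif_knockout_prob probability a pseudogene's 5.8S motif is
#'   destroyed (3 substitutions).
#' @param indel_rate_multiplier pseudogene indel-count multiplier.
#' @param n_func_indels expected functional-clade indel events.
#' @param n_recombinants chimeric sequences spliced from a functional and a
#'   pseudogene parent.
#' @param breakpoint optional `c(min, max)` column range for recombination
#'   breakpoints (default: uniform over interior columns).
#' @param r5_8s_rate_factor relative substitution rate of the 5.8S region
#'   in functional copies (purifying constraint); pseudogenes relax to 1.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 8L, n_functional = 2L, n_pseudogene = 1L,
                       seq_lengths = c(its1 = 230L, r5_8s = 160L, its2 = 240L),
                       model = subst_model("GTR",
                                           rates = c(1, 2.5, 1, 1, 2.5, 1),
                                           freqs = c(0.22, 0.28, 0.28, 0.22),
                                           gamma = TRUE, alpha = 0.5),
                       tree_depth = 0.08, clone_depth = 0.01,
                       rate_multiplier = 3.0, gc_shift = -0.12,
                       motif_knockout_prob = 0.9,
                       indel_rate_multiplier = 4.0, n_func_indels = 2,
                       n_recombinants = 2L, breakpoint = NULL,
                       r5_8s_rate_factor = 0.3) {
  stopifnot(n_species >= 2L, n_functional >= 1L, n_pseudogene >= 0L,
            rate_multiplier > 0, motif_knockout_prob >= 0,
            motif_knockout_prob <= 1, indel_rate_multiplier > 0,
            all(seq_lengths > 0))
  structure(as.list(environment()), class = "sim_config")
}

# shift equilibrium frequencies toward A/T by `shift` total GC mass
.shift_freqs <- function(freqs, shift) {
  gc <- freqs[2] + freqs[3]
  at <- freqs[1] + freqs[4]
  d <- min(-shift, gc - 0.02)     # shift < 0 moves mass to A/T
  f <- freqs
  f[c(2, 3)] <- f[c(2, 3)] * (gc - d) / gc
  f[c(1, 4)] <- f[c(1, 4)] * (at + d) / at
  f / sum(f)
}

# evolve integer-coded sequences down a rooted phylo; rates: per-site rate
# vector; eig may differ per clade via `eig_for(node)`
.evolve <- function(phy, root_seq, site_rates, eig_fun, rate_fun) {
  nt <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  # preorder: reverse postorder
  seqs <- vector("list", nt + phy$Nnode)
  seqs[[nt + 1L]] <- root_seq
  n <- length(root_seq)
  for (k in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[k, 1]; ch <- po$edge[k, 2]
    t <- po$edge.length[k] * rate_fun(ch)
    eig <- eig_fun(ch)
    s <- seqs[[p]]
    out <- integer(n)
    for (r in unique(site_rates)) {
      idx <- which(site_rates == r)
      P <- .pmat(eig, t, r)
      for (st in 1:4) {
        ii <- idx[s[idx] == st]
        if (length(ii))
          out[ii] <- sample.int(4, length(ii), replace = TRUE, prob = P[st, ])
      }
    }
    seqs[[ch]] <- out
  }
  seqs
}

#' Simulate an ITS paralog family with known truth
#'
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return List with `alignment` (a [ribo_alignment]), and `truth`: a data
#'   frame of per-sequence labels (`functional`, `pseudogene`,
#'   `recombinant`) with recombination parents and breakpoints, the true
#'   paralog `tree` (recombinants excluded), the functional/pseudogene tip
#'   sets, planted `indels`, per-species `areas` and the species tree.
#' @export
simulate_family <- function(config = sim_config(), seed = 1L) {
  cf <- config
  n_seq_total <- cf$n_species * (cf$n_functional + cf$n_pseudogene)
  if (cf$n_recombinants > n_seq_total)
    stop("infeasible config: more recombinants than sequences")
  if (cf$n_recombinants > 0L && (cf$n_pseudogene < 1L || cf$n_functional < 1L))
    stop("infeasible config: recombinants need functional and pseudogene parents")
  with_seed(seed, {
    L <- sum(cf$seq_lengths)
    b1 <- cf$seq_lengths[["its1"]]
    b2 <- b1 + cf$seq_lengths[["r5_8s"]]
    # species tree (coalescent shape scaled to the configured depth)
    sp_tree <- ape::rcoal(cf$n_species, tip.label = paste0("sp", seq_len(cf$n_species)))
    sp_tree$edge.length <- sp_tree$edge.length *
      cf$tree_depth / max(ape::node.depth.edgelength(sp_tree))
    # paralog gene tree: functional + pseudogene mirror subtrees
    clone_nwk <- function(sp, pref, k) {
      lab <- paste0(sp, "_", pref, seq_len(k))
      if (k == 1L) return(paste0(lab, ":", cf$clone_depth))
      paste0("(", paste0(lab, ":", cf$clone_depth / 2, collapse = ","), "):",
             cf$clone_depth / 2)
    }
    graft <- function(pref, k) {
      txt <- ape::write.tree(sp_tree)
      for (sp in sp_tree$tip.label) {
        # replace "spN:" tip with clone subtree keeping the species branch
        txt <- sub(paste0(sp, ":"), paste0("(", clone_nwk(sp, pref, k), "):"),
                   txt, fixed = TRUE)
      }
      sub(";$", "", txt)
    }
    stem <- cf$tree_depth / 2
    gene_nwk <- paste0("(", graft("f", cf$n_functional), ":", stem, ",",
                       graft("p", cf$n_pseudogene), ":", stem, ");")
    gene_tree <- ape::collapse.singles(ape::read.tree(text = gene_nwk))
    func_ids <- grep("_f", gene_tree$tip.label, value = TRUE)
    pseudo_ids <- grep("_p", gene_tree$tip.label, value = TRUE)
    # root sequence: random ITS1/ITS2 from equilibrium, reference 5.8S
    f0 <- cf$model$freqs
    ref58 <- .encode_seq(.REF_5_8S)[seq_len(cf$seq_lengths[["r5_8s"]])]
    root_seq <- c(sample.int(4, b1, replace = TRUE, prob = f0),
                  ref58,
                  sample.int(4, cf$seq_lengths[["its2"]], replace = TRUE,
                             prob = f0))
    # per-site rates: gamma categories; 5.8S additionally slowed in the
    # functional subtree (handled via region factor in site rates and a
    # pseudogene relaxation below)
    cats <- gamma_rates(cf$model$alpha, cf$model$ncat)
    site_rates <- sample(cats, L, replace = TRUE)
    region_factor <- rep(1, L)
    region_factor[(b1 + 1L):b2] <- cf$r5_8s_rate_factor
    # the 14-bp motif is effectively invariant while the copy is functional
    # (it is conserved across seed plants); pseudogenes relax it entirely
    region_factor[(b1 + 42L):(b1 + 41L + nchar(.MOTIF_5_8S))] <- 0.002
    # clade membership: tips/nodes in the pseudogene subtree
    nt <- length(gene_tree$tip.label)
    sets <- .node_tipsets(gene_tree)
    in_pseudo <- vapply(seq_len(nt + gene_tree$Nnode), function(nd)
      all(sets[[nd]] %in% pseudo_ids), TRUE)
    eig_func <- .model_eigen(cf$model)
    mp <- cf$model; mp$freqs <- .shift_freqs(cf$model$freqs, cf$gc_shift)
    eig_pseudo <- .model_eigen(mp)
    # functional copies: slowed 5.8S; pseudogenes: relaxed 5.8S + rate x
    seqs_f <- .evolve(gene_tree, root_seq, site_rates * region_factor,
                      eig_fun = function(nd) eig_func,
                      rate_fun = function(nd) 1)
    # re-evolve pseudogene subtree from its stem ancestor with its own
    # process (relaxed 5.8S, shifted equilibrium, rate multiplier)
    pseudo_root <- which(vapply(seq_len(nt + gene_tree$Nnode), function(nd)
      setequal(sets[[nd]], pseudo_ids), TRUE))
    seqs <- seqs_f
    if (length(pseudo_ids)) {
      sub_nodes <- which(in_pseudo)
      # evolve the whole tree again under pseudogene process but only keep
      # pseudogene-subtree results, starting from the functional-process
      # state at the pseudogene stem's parent (the root)
      seqs_p <- .evolve(gene_tree, root_seq, site_rates,
                        eig_fun = function(nd) eig_pseudo,
                        rate_fun = function(nd) cf$rate_multiplier)
      for (nd in sub_nodes) seqs[[nd]] <- seqs_p[[nd]]
    }
    chars <- c("A", "C", "G", "T")
    rows <- vapply(seq_len(nt), function(i)
      .v2s(chars[seqs[[i]]]), "")
    ids <- gene_tree$tip.label
    names(rows) <- ids
    # motif knockout in pseudogenes
    mstart <- b1 + 42L                      # motif offset 41 in the 5.8S ref
    mlen <- nchar(.MOTIF_5_8S)
    knocked <- character(0)
    for (id in pseudo_ids) {
      if (runif(1) <= cf$motif_knockout_prob) {
        v <- .s2v(rows[[id]])
        pos <- mstart + sample.int(mlen, 3L) - 1L
        for (p in pos) v[p] <- sample(setdiff(chars, v[p]), 1)
        rows[[id]] <- .v2s(v)
        knocked <- c(knocked, id)
      }
    }
    # planted indels: deletions shared by the tips of a random clade,
    # restricted to the ITS regions, non-overlapping
    n_f_ind <- rpois(1, cf$n_func_indels)
    n_p_ind <- rpois(1, cf$n_func_indels * cf$indel_rate_multiplier)
    occupied <- matrix(FALSE, 1, L)
    indels <- data.frame(start = integer(0), end = integer(0),
                         carriers = character(0))
    pick_interval <- function() {
      for (try in 1:50) {
        len <- sample(3:12, 1)
        in_its1 <- runif(1) < 0.5
        lo <- if (in_its1) 20L else b2 + 5L
        hi <- if (in_its1) b1 - len - 5L else L - len - 20L
        if (hi <= lo) next
        s <- sample(lo:hi, 1)
        if (!any(occupied[1, (s - 1L):(s + len + 1L)])) {
          occupied[1, s:(s + len - 1L)] <<- TRUE
          return(c(s, s + len))            # 1-based start, half-open end+1
        }
      }
      NULL
    }
    clade_tips <- function(pool_ids) {
      cand <- which(vapply(seq_len(nt + gene_tree$Nnode), function(nd)
        length(sets[[nd]]) >= 1 && all(sets[[nd]] %in% pool_ids), TRUE))
      sets[[cand[sample.int(length(cand), 1)]]]
    }
    add_indels <- function(n, pool_ids, indels) {
      for (i in seq_len(n)) {
        iv <- pick_interval()
        if (is.null(iv)) next
        tipsc <- clade_tips(pool_ids)
        for (id in tipsc) {
          v <- .s2v(rows[[id]])
          v[iv[1]:(iv[2] - 1L)] <- "-"
          rows[[id]] <<- .v2s(v)
        }
        indels <- rbind(indels, data.frame(
          start = iv[1] - 1L, end = iv[2] - 1L,
          carriers = paste(sort(tipsc), collapse = ",")))
      }
      indels
    }
    indels <- add_indels(n_f_ind, func_ids, indels)
    if (length(pseudo_ids)) indels <- add_indels(n_p_ind, pseudo_ids, indels)
    # recombinants: functional head + pseudogene tail (or vice versa)
    rec <- data.frame(id = character(0), parent_head = character(0),
                      parent_tail = character(0), breakpoint = integer(0))
    if (cf$n_recombinants > 0L) {
      for (i in seq_len(cf$n_recombinants)) {
        pf <- sample(func_ids, 1); pp <- sample(pseudo_ids, 1)
        bp <- if (!is.null(cf$breakpoint))
          sample(cf$breakpoint[1]:cf$breakpoint[2], 1)
        else sample(seq(40L, L - 40L), 1)
        head_p <- if (runif(1) < 0.5) pf else pp
        tail_p <- if (head_p == pf) pp else pf
        rid <- paste0("rec", i)
        rows[[rid]] <- paste0(substr(rows[[head_p]], 1, bp),
                              substr(rows[[tail_p]], bp + 1L, L))
        rec <- rbind(rec, data.frame(id = rid, parent_head = head_p,
                                     parent_tail = tail_p, breakpoint = bp))
      }
    }
    ids_all <- c(ids, rec$id)
    aln <- ribo_alignment(ids_all, unlist(rows[ids_all]),
                          region_map = list(its1 = c(0L, b1),
                                            r5_8s = c(b1, b2),
                                            its2 = c(b2, L)))
    # clade-structured area labels on the species tree
    sp_sets <- .node_tipsets(sp_tree)
    root_ch <- sp_tree$edge[sp_tree$edge[, 1] == cf$n_species + 1L, 2]
    g1 <- sp_sets[[root_ch[1]]]; g2 <- sp_sets[[root_ch[2]]]
    big <- if (length(g1) >= length(g2)) g1 else g2
    small <- setdiff(sp_tree$tip.label, big)
    half <- ceiling(length(big) / 2)
    areas <- data.frame(taxon = sp_tree$tip.label, areas = "A",
                        stringsAsFactors = FALSE)
    areas$areas[areas$taxon %in% small] <- "A"
    areas$areas[areas$taxon %in% big[seq_len(half)]] <- "B"
    areas$areas[areas$taxon %in% setdiff(big, big[seq_len(half)])] <- "C"
    labels <- data.frame(
      id = ids_all,
      class = c(ifelse(ids %in% pseudo_ids, "pseudogene", "functional"),
                rep("recombinant", nrow(rec))),
      motif_knocked = ids_all %in% knocked,
      stringsAsFactors = FALSE)
    truth <- list(labels = labels, tree = gene_tree,
                  functional = func_ids, pseudogenes = pseudo_ids,
                  recombinants = rec, indels = indels,
                  species_tree = sp_tree, areas = areas,
                  seed = seed, config = cf)
    list(alignment = aln, truth = truth)
  })
}

#' Simulate a null (tract-free) sequence pair
#'
#' Two sequences with independent site-wise divergence and no conversion
#' tract; the null model for the recombination test's type-I error.
#'
#' @param divergence expected p-distance in `(0, 0.75)`.
#' @param length sequence length.
#' @param seed RNG seed.
#' @return A [ribo_alignment] of 2 rows (`s1`, `s2`).
#' @export
simulate_null_pair <- function(divergence, length = 500L, seed = 1L) {
  stopifnot(divergence > 0, divergence < 0.75)
  with_seed(seed, {
    chars <- c("A", "C", "G", "T")
    a <- sample(chars, length, replace = TRUE)
    b <- a
    flip <- runif(length) < divergence
    b[flip] <- vapply(a[flip], function(x) sample(setdiff(chars, x), 1), "")
    ribo_alignment(c("s1", "s2"), c(.v2s(a), .v2s(b)))
  })
}

#' Simulate area presence at tips (and true node states) on a tree
#'
#' Evolves each area as an independent two-state character under the same
#' F81-style binary CTMC with gamma rate variation that [bbm_ancestral()]
#' assumes; used to test ancestral-range recovery against known truth.
#'
#' @param tree a rooted `phylo`.
#' @param freqs per-area stationary presence frequencies.
#' @param alpha gamma shape shared across areas.
#' @param area_names area labels.
#' @param seed RNG seed.
#' @return List with `areas` (taxon/areas data frame), `node_states`
#'   (Nnode x areas 0/1 matrix), `root_range` (character subset at the
#'   root).  Tips or nodes with empty ranges are resampled jointly until
#'   non-empty (a lineage occupies >= 1 area).
#' @export
simulate_areas <- function(tree, freqs = c(0.5, 0.4, 0.3), alpha = 1,
                           area_names = c("A", "B", "C"), seed = 1L) {
  stopifnot(length(freqs) == length(area_names))
  nt <- length(tree$tip.label)
  with_seed(seed, {
    for (attempt in 1:200) {
      states <- matrix(0L, nt + tree$Nnode, length(freqs))
      rts <- gamma_rates(alpha, 4L)
      for (a in seq_along(freqs)) {
        frq <- c(1 - freqs[a], freqs[a])
        eig <- .model_eigen(binary_model(freqs = frq, gamma = FALSE))
        r <- sample(rts, 1)
        po <- ape::reorder.phylo(tree, "postorder")
        st <- integer(nt + tree$Nnode)
        st[nt + 1L] <- as.integer(runif(1) < frq[2])
        for (k in rev(seq_len(nrow(po$edge)))) {
          p <- po$edge[k, 1]; ch <- po$edge[k, 2]
          P <- .pmat(eig, po$edge.length[k], r)
          st[ch] <- as.integer(runif(1) < P[st[p] + 1L, 2])
        }
        states[, a] <- st
      }
      if (all(rowSums(states) >= 1L)) break
    }
    # any lineage still empty after resampling gets its highest-frequency area
    empty <- rowSums(states) == 0L
    states[empty, which.max(freqs)] <- 1L
    tip_areas <- vapply(seq_len(nt), function(i)
      paste(area_names[states[i, ] == 1L], collapse = ""), "")
    list(areas = data.frame(taxon = tree$tip.label, areas = tip_areas,
                            stringsAsFactors = FALSE),
         node_states = states[(nt + 1L):(nt + tree$Nnode), , drop = FALSE],
         root_range = paste(area_names[states[nt + 1L, ] == 1L], collapse = ""))
  })
}
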