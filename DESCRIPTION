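Package: ribosort
Title: Classification and Phylogenetic Analysis of Divergent Ribosomal ITS Paralogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing non-concerted evolution of nuclear ribosomal DNA
    internal transcribed spacer (ITS) paralog families. Classifies cloned ITS
    copies into functional paralogs and putative pseudogenes from per-region GC
    content, presence of the conserved 14-bp 5.8S motif, secondary-structure
    stability and relative evolutionary rate; detects recombinant (chimeric)
    copies with a Sawyer-type inner-fragment statistic and permutation null;
    codes alignment gaps as binary characters by simple indel coding; computes
    GTR+G and binary restriction-site (variable-coding) likelihoods by
    Felsenstein pruning, with AIC model choice, NNI maximum-likelihood tree
    search, nonparametric bootstrap, Metropolis-coupled Bayesian MCMC with
    split-frequency convergence diagnostics and majority-rule consensus;
    roots functional-paralog phylogenies on pseudogene molecular outgroups; and
    reconstructs ancestral geographic ranges over a posterior tree sample by a
    Bayesian binary MCMC with a maximum-areas constraint. A seeded simulator
    generates ITS paralog families with known truth (labels, breakpoints,
    trees, areas) so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
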