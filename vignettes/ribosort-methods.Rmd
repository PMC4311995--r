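---
title: "Sorting divergent ribosomal ITS paralogs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting divergent ribosomal ITS paralogs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribosort)
```

## The problem

Nuclear ribosomal DNA occurs in long tandem arrays whose repeats are
normally homogenised by unequal crossing over and gene conversion
("concerted evolution").  When homogenisation fails, a single genome
accumulates divergent ITS (ITS1–5.8S–ITS2) paralogs: functional copies
under purifying selection, decayed pseudogenes, and chimeric recombinants
spliced from two parent copies.  Cloned ITS data sets from such genomes
mix all three, and using them naively in phylogenetics produces spurious
relationships.  `ribosort` implements the full desk-side workflow for this
situation: classify the clones, screen for recombinants, infer trees from
the functional copies with the pseudogenes as a *molecular outgroup*, and
reconstruct ancestral geographic ranges over the posterior tree sample.
A seeded simulator produces paralog families with known truth so that every
stage is testable without any external data.

## Classification of paralogs

Pseudogenes decay in predictable ways, and each symptom casts one vote:

* **GC content** drifts downwards once selection stops opposing AT-biased
  mutation.  The classifier computes per-region and whole-sequence GC
  (gaps and N excluded from numerator and denominator) and scores each
  sequence by a *robust z-score* (median/MAD) against a provisional
  functional pool; a vote is cast at `z <= -2` (`gc_z_cut`).  Median/MAD is
  used because the pools are small (tens of sequences) and a single
  mislabelled sequence should not drag a mean-based baseline.
* **The conserved 14-bp 5.8S motif** `GAATTGCAGAATCC` is scanned with a
  Hamming-distance window (leftmost best window; gaps deleted first).  A
  sequence missing the motif within the mismatch budget (default 1) votes
  pseudogene.
* **Secondary-structure stability** of the 5.8S is scored with a
  Nussinov-style nested-structure dynamic program: Watson–Crick pairs −1,
  −2 when stacked directly on another pair, G:T wobble −0.5, hairpin loops
  of at least 3 bases.  This is deliberately *not* a nearest-neighbour
  thermodynamic model: only the relative stability between paralogs of the
  same gene matters for the vote, the score is exactly reproducible, and it
  is verifiable against brute-force enumeration of all nested structures
  (the test suite does exactly that for short sequences).  The vote is
  again a robust z-score (`z >= 2` means "less stable than the pool").
* **Relative evolutionary rate**: mean p-distance from the focal sequence
  to the provisional pool divided by the mean pairwise p-distance within
  the pool; a ratio of 2 or more votes pseudogene.  On a symmetric star
  geometry the expected ratio for a focal lineage evolving `m` times faster
  is `(m+1)/2`, so the ratio underestimates the branch-rate multiplier;
  in practice pseudogene clades are deeply diverged from the functional
  pool and the ratio is far above the cutoff.

The provisional functional pool (pass 1) is simply "motif present"; at
least 3 such sequences are required.  A sequence is called a pseudogene
when **at least 2 of the 4 criteria** vote for it.  The voting rule, the
robust-z definition of "significantly lower", and the cutoffs are package
choices: the field's criteria lists are qualitative, and we wanted a rule
that is monotone (loosening a cutoff can only grow the pseudogene set — a
property test), order-invariant, and fully reproducible.  Sequence length
and substitution counts are reported as features but do not vote by
default.

Region boundaries (ITS1 | 5.8S | ITS2) are located by anchoring the 14-bp
motif inside a 160-nt synthetic reference 5.8S (a constructed stand-in
with realistic composition, not a database sequence) with up to 2
mismatches.  Sequences that fail to anchor — decayed pseudogenes may lose
the motif entirely — keep proportional fallback regions (40% / 15% / 45%)
and carry an `anchored = FALSE` flag, because they still need per-region GC
for classification.  The ITS1 interval always starts at position 0 (it is
the prefix by definition), so prepending residues shifts every boundary
except that one.

## Recombination screening

Chimeric copies are detected with a Sawyer-type inner-fragment statistic.
For each sequence pair, the match/mismatch profile over informative columns
is scanned for the maximal-scoring contiguous segment, where each match
scores +1 and the *j*-th mismatch within the segment scores `−g·j`
(quadratic ramp).  The default `g = Inf` admits no mismatches, so
fragments are maximal identical runs — the classic inner-fragment
convention, and by a longest-run argument the most powerful choice against
clean conversion tracts; finite `g` is the documented relaxation for
noisier data.  Because the ramp penalty depends on the segment's own
mismatch count, the classic linear-scan reset is not guaranteed optimal;
the implementation is an exact incremental scan over all start positions
(C++), and the tests verify equality with an independent brute-force
search over all intervals.

Significance comes from a permutation null: informative-column order is
shuffled identically for both rows, and
`p = (1 + #{permutation max >= observed}) / (n_perm + 1)`.  For alignments
of three or more rows the informative columns are the polymorphic columns;
for a bare pair "polymorphic" degenerates to "mismatch" (which would make
the statistic identically zero), so all mutually comparable columns are
used instead.  Pairwise p-values are Bonferroni-corrected over the number
of pairs (the global-style correction); note that this makes significance
*unattainable* unless `n_perm > n_pairs / alpha` — the permutation p-value
cannot fall below `1/(n_perm+1)` — and `detect_recombinants()` warns when
`n_perm` is too small for the family at hand.  Permutation scans stop
early once a pair can no longer reach significance; the early-stopped
p-values are conservative truncations whose accept/reject decision is
exact.

Attributing a significant pair to *which* member is the chimera uses the
sharp-discontinuity signature: for each member (with the partner excluded
from the candidate pool), nearest neighbours are computed separately left
and right of the fragment (a fragment touching an alignment end uses the
fragment interior as the missing side).  The member is flagged when the two
flank neighbours differ *and* each flank's neighbour beats the other
flank's neighbour by at least 0.10 p-distance on its own flank (the
"crossing" margin — a chimera's flank matches its donor lineage tightly,
whereas a parent's neighbours flip only by noise).  A second pass repeats
the attribution with all first-pass candidates removed from the neighbour
pool: without it, a chimera sitting in the pool fakes flank discordance
for its own parent.

## Indel coding

Alignment gaps are converted to a binary partition by simple indel coding:
every distinct internal `(start, end)` gap span is one character; a row
scores 1 for an exactly matching gap run, `?` (inapplicable, treated as
missing) when one of its runs strictly contains the span, and 0 otherwise.
Terminal gap runs are treated as missing data, not indels — common
practice, since leading/trailing gaps usually reflect incomplete reads.
Characters in which no row scores 0 are emitted but flagged constant;
variable-coding likelihoods drop them.

## Likelihoods, tree search and Bayesian inference

The DNA partition is scored by Felsenstein pruning under the GTR family
with discrete-gamma rate variation: 4 equal-probability categories at the
quantile medians of Gamma(α, α), normalised to mean 1.  Gaps and N are
marginalised.  The binary indel partition uses a two-state CTMC with its
own stationary frequencies and gamma shape; under `coding = variable` each
character's likelihood is divided by `1 − P(all 0) − P(all 1)` — the
ascertainment correction required because constant indel characters are
not recorded.  The tests assert the exact algebraic identity
`L_cond · P(variable) = L_uncond` rather than any inequality (the naive
"conditioning lowers the likelihood" is false in general), and check the
pruning likelihood against a brute-force sum over all internal-node state
assignments and against an independent implementation.

Model choice is by AIC on a fixed NJ evaluation tree, with each
candidate's free parameters (exchangeabilities, frequencies, gamma shape,
plus an uncounted shared branch-length scale) fitted numerically.

The ML search starts from the NJ tree (JC distances) and hill-climbs with
nearest-neighbour interchanges, giving each accepted move a full
branch-length optimisation sweep (Brent per branch, lnL tolerance 1e-6,
first-best tie rule in canonical split order).  No SPR and no performance
targets beyond desk scale: on six taxa the search is verified against
exhaustive evaluation of all 105 topologies.  Bootstrap supports resample
DNA columns and binary characters within their partitions and map split
frequencies back onto the ML tree.

Bayesian inference is a Metropolis-coupled MCMC (1 cold + heated chains,
`beta_i = 1/(1 + 0.1 i)`) over topology (uniform random NNI), branch
lengths (multiplier), GTR exchangeabilities and frequencies (Dirichlet
proposals with exact Hastings ratios), and the gamma shapes.  Priors are
MrBayes-like: iid Exponential(10) branch lengths, flat Dirichlets, and
Exponential(1) shapes.  Convergence between independent runs is summarised
by the average standard deviation of split frequencies (splits at
frequency ≥ 0.10 in either run); posterior topologies are summarised as a
strict majority-rule consensus (frequency > 0.5, no greedy addition), with
clade posterior probabilities equal to exact split frequencies and branch
lengths averaged over the trees containing each split.  The two-taxon
branch-length posterior is validated against numeric integration of the
exact posterior; determinism given a seed is asserted directly.

Rooting uses the pseudogenes as a molecular outgroup: when the outgroup
tips form one side of a split, the root is placed at the midpoint of that
branch; otherwise the function *errors*, reporting the smallest clade
containing the outgroup — it never silently forces monophyly.  In the
pipeline's biogeographic stage, individual posterior trees (in which the
outgroup need not be monophyletic sample by sample) are instead rooted on
a single designated pseudogene clone before the outgroup is pruned.

## Ancestral ranges (Bayesian binary MCMC)

Each area (A/B/C) is an independent two-state presence/absence character
under an F81-style binary CTMC (stationary presence frequency per area)
with shared discrete-gamma rate variation — our concrete reading of
"F81 + G" for binary range data.  Over each tree of the posterior sample,
a small heated MCMC samples the per-area frequencies (sliding window plus
flat-prior independence draws; the independence proposal is what keeps the
chain mixing when few tips constrain a frequency) and the shared shape;
at each sampled state, node states are drawn by pruning followed by
stochastic traceback, and per-node area subsets are pooled across draws
and trees, with nodes matched by tip set and reported with their coverage
fraction.  Empty ranges (a lineage occupying no area) are excluded from
the pooled counts — equivalently, renormalised out.  Subsets larger than
`max_areas` have their probability reassigned proportionally to their
highest-marginal subsets of allowed size; with three areas and
`max_areas = 3` (the default configuration) this is a no-op.  How the
reference implementations aggregate per-area posteriors into range
probabilities is not documented anywhere we could verify, so this
aggregation rule is stated here and flagged in the output rather than
hidden.

## The simulator

`simulate_family()` generates the data the analysis assumes: a coalescent
species tree (default depth 0.08 expected substitutions/site) carrying a
paralog gene tree with one functional and one mirrored pseudogene subtree
joined at the root — functional and pseudogene copies are reciprocally
monophyletic by construction, which is exactly the regime in which a
pseudogene outgroup is defensible.  Functional copies evolve under GTR+G
with the 5.8S slowed to 0.3× (purifying constraint) and the 14-bp motif
embedded in a synthetic reference 5.8S; pseudogene lineages get a 3× rate
multiplier, an equilibrium composition shifted 0.12 toward A/T, motif
knockout with probability 0.9 (three substitutions in the motif), and a
4× indel rate.  Indels are deletions planted on clades of the gene tree
(so they nest and share breakpoints the way real indels do), kept clear of
the alignment ends and the 5.8S.  Recombinants are spliced post hoc from a
functional and a pseudogene parent at a drawn breakpoint.  The emitted
alignment is the true simulated homology — no aligner is involved, so
tests of downstream stages are not confounded by alignment error.  Default
family size is 8 species × (2 functional + 1 pseudogene) + 2 recombinants:
large enough for pool statistics and clade structure, small enough that the
full pipeline runs in minutes.

What the simulator does *not* emulate: alignment uncertainty, PCR and
sequencing error, within-array copy-number variation, and partial
gene-conversion homogenisation dynamics.  Passing tests therefore show the
machinery is correct under the stated model, not that real cloned data
meet the model.

## Problem sizes and numerical choices

Tests and the acceptance script use deliberately scaled-down run lengths,
chosen as the package's own desk-scale study conditions: MCMC runs of a
few thousand generations on families of 15–26 sequences (the settings
constructors default to the field-standard 2 million generations sampled
every 100), permutation tests with 199–7,999 permutations sized to the
number of pairs being corrected over, 25-replicate classifier and
8-replicate chimera batteries, and BBM runs of 20,000–60,000 generations.
The BBM recovery battery simulates areas on 8-taxon coalescent trees
scaled to 0.1 expected transitions root-to-tip with presence frequencies
(0.45, 0.35, 0.25) and shape 2 — a regime in which tip ranges still carry
substantial information about the root, because the battery is meant to
measure the correctness of the reconstruction machinery, not the
(genuine) unrecoverability of deep ancestral states on saturated trees.

Other numerical choices: branch lengths are clamped below at 1e-9 (1e-6
after NJ, whose estimates can be negative); pairwise p-distances ignore
columns with gaps or N in either row; robust scales fall back from MAD to
the standard deviation (and then to a small epsilon) when the pool is
degenerate, so all-identical inputs classify as functional with zero
votes; consensus ties at exactly 0.5 are excluded by the strict `> 0.5`
rule; and every stochastic function takes an explicit seed and restores
the caller's RNG state.

## Known limitations

* The fold score is a base-pairing count with stacking, not a free energy
  in kcal/mol; it must only rank paralogs of the same gene.
* The recombination screen tests pairs; mosaic sequences with more than
  two donors are flagged but their breakpoints are summarised per pair.
* The ML search is NNI-only and can in principle stop at an NNI-local
  optimum; the six-taxon exhaustive comparison bounds how often that
  happens at desk scale.
* BBM range probabilities depend on the stated subset-aggregation rule;
  other aggregation conventions will give different percentages on the
  same sample.
* At the scale of hundreds of taxa the likelihood engine (pure R with
  small C++ kernels) is not competitive with dedicated ML/BI programs, and
  is not meant to be.
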