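---
title: "Computational irreproducibility of ML phylogenies at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational irreproducibility of ML phylogenies at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The phenomenon

Maximum-likelihood (ML) tree inference is carried out by heuristic search:
the universe of unrooted binary topologies grows as $(2m-5)!!$ with the
number of taxa $m$, so programs climb from a handful of starting trees by
topological rearrangement, accepting moves that raise the log-likelihood.
Run the same program twice on the same alignment under the same model and
settings, changing only the random seed, and the two runs may return
*different* trees: computational irreproducibility.  `optforest` is a
self-contained laboratory for studying this phenomenon.  It simulates
alignments on known trees, infers trees twice with an internal seeded ML
engine, and asks the questions that matter downstream:

* Are the two trees $Q_1$ and $Q_2$ more different from each other than
  either is from the true tree $T$?
* Do the inferred trees have log-likelihoods inferior to the true tree's?
* Does a search that is guaranteed to explore the true tree's
  neighborhood (the $Q_3$ protocol) produce a more accurate tree?
* How do irreproducibility and the "optimality forest" — the set of
  distinct topologies whose optimized log-likelihood exceeds the true
  tree's — depend on the amount of phylogenetic information in the data?

Topological disagreement is measured by the Robinson–Foulds distance
$d_{RF}$ on non-trivial splits, reported as the percentage
$d_{RF} / (2(m-3)) \times 100$ of its maximum for fully resolved trees.
Phylogenetic information is the expected substitution count: the sum of
the true tree's branch lengths (substitutions/site) times the alignment
length.

## The engine

The likelihood core is Felsenstein pruning over compressed site patterns
under reversible nucleotide models (HKY or GTR), with "+G4" discrete-gamma
rate heterogeneity: four equal-probability categories whose rates are the
means of the quantile bins of a mean-one gamma distribution.  All
log-likelihoods are natural logs.  The rate matrix is scaled to one
expected substitution per site per unit branch length, and transition
matrices come from the symmetrized eigendecomposition of $Q$, so the
unrooted likelihood is invariant to where the computation is rooted.
Numerical choices: per-node partial rescaling guards against underflow;
branch lengths are constrained to $[10^{-8}, 10]$; per-branch optimization
is safeguarded Newton–Raphson on the analytic first and second derivatives
of the branch log-likelihood (with Brent's method as fallback), swept
round-robin over branches until a full sweep improves the log-likelihood
by less than `epsilon` (default $10^{-4}$, matching the optimization
epsilon of the reference protocol).  Each per-branch step never decreases
the likelihood, so sweep traces are monotone.

The search is greedy steepest-ascent hill climbing under
nearest-neighbor-interchange (NNI) moves.  Candidates are screened by a
quick pass that re-optimizes only the five branches the NNI move touches
(warm-started from the inherited lengths, so the screening score is a
lower bound of the candidate's fully optimized score); the best candidate
is then fully re-optimized and accepted only if it improves the incumbent
by more than `epsilon`.  Starting trees mix parsimony stepwise-addition
under random taxon orders with neighbor-joining on bootstrap-resampled
site columns; their seed-dependence is the mechanism of
irreproducibility.  Sampled SPR rearrangements can be added by
configuration, but NNI suffices to generate every phenomenon studied here
at these tree sizes.

Two tie-break rules make the engine reproducible yet seed-sensitive, the
combination the phenomenon requires: within a climb, neighbor order is
seed-shuffled with first-index tie-breaking; across starts, results whose
log-likelihoods tie within `epsilon` are reported according to a
seed-shuffled start order.  Without the second rule, a search seeded with
the true tree would return the true tree whenever the likelihood surface
is flat — an artifact: on plateaus, real programs drift through their
perturbation cycles rather than privileging the initial tree.  For the
same reason, when an initial tree is supplied the engine still generates
its usual candidate starts (as reference implementations do), rather than
only perturbing the initial tree.

`exhaustive_search` optimizes every topology (enumeration is guarded at
$m \le 8$) and serves as the global-optimum oracle; it uses a tighter
convergence epsilon ($10^{-6}$) than the heuristic so that its score
dominates heuristic scores up to convergence slack.

## The simulation designs

Both study designs are emulated at desk scale by `make_collection`; every
data set draws its own parameters and seed from a master seed by counter,
so any single data set can be regenerated in isolation.

**The 100-data set design** (`design_hundred()`): 100 alignments of 16
taxa under HKY, sequence lengths 258–2,000 sites, G+C content 0.39–0.82
(stationary frequencies $((1-GC)/2, GC/2, GC/2, (1-GC)/2)$),
transition/transversion ratios 1.35–2.6, lineage rates 0.81–3.95
$\times 10^{-9}$ substitutions/site/year.  Each true tree is a fresh Yule
topology whose branch durations total 30–150 million years; lineage rates
follow an autocorrelated lognormal model (child log-rates normal around
the parent's with variance 0.04 per 100 My of branch duration — these
hyperparameters are not fixed by the protocol being emulated and are
configurable).  The resulting collections span roughly 35–900 expected
substitutions: the low-information regime in which irreproducibility
lives.  The reference study used one fixed 142-taxon empirical topology
and far longer alignments; at 16 taxa that regime would be trivially easy,
so tree depth is scaled down to preserve the *relationship* between
information, irreproducibility, and accuracy rather than any particular
percentage.

**The informativeness ladder** (`design_ladder()`): levels of target
expected-substitution counts, geometrically spaced (the spacing of the
original levels is not published; geometric spacing covers the range
evenly on the scale that matters), each level holding `n_per_level` GTR+G4
(shape 1.0) data sets.  Each data set draws a moderate tree length
(0.4–2.5 substitutions/site) and takes its alignment length from the
information target.  Scaling information through sites at moderate branch
lengths is essential: holding sites fixed and stretching branches instead
saturates the alignment at high levels and makes inference *harder*
again, inverting every information trend.

What the simulations deliberately leave out: indels (alignments are
gap-free, matching the emulated protocol), codon/amino-acid models,
model-selection steps, and topology estimation error in the reference
tree (the true tree is known exactly).  Passing tests therefore show that
the *patterns* — not the published percentages, which belong to specific
deposited data sets run through specific third-party programs — are
reproduced by an independent engine under matched study conditions.

## The protocols

```{r}
library(optforest)

col <- make_collection(design_hundred())
tw  <- two_run_collection(col)          # run seeds 111 and 123
aggregate_runs(tw)

q3  <- true_start_collection(col, tw, search_config(seed = 311L))

lad <- make_collection(design_ladder(n_levels = 3, n_per_level = 12,
                                     info_range = c(150, 9600)))
forests <- lapply(lad$datasets, function(x)
  build_forest(x$alignment, x$model, x$tree, n_starts = 6, seed = x$seed))
```

`two_run` performs the two-seed protocol (identical seeds are refused:
they would mandatorily reproduce).  `true_start_run` implements the $Q_3$
experiment.  `build_forest` runs seeded hill climbs from bootstrap-derived
starts with full trace retention — every evaluated candidate, accepted or
rejected, is kept — deduplicates topologies by canonical splits, fully
re-optimizes branch lengths per distinct topology, and keeps those that
strictly beat the optimized true tree.  Re-optimization is restricted to
pooled topologies whose screening score exceeds the true tree's optimized
log-likelihood minus a 10-unit guard; since screening scores are lower
bounds of re-optimized scores, a member could only be missed if its quick
score undershot its full score by more than 10 log-units, far beyond what
single-NNI screening leaves on the table.  The forest's *breadth* is the
log-likelihood gap between the best tree found and the true tree (the
"final inferred tree" variant of that gap is available from the search
results directly); empty forests contribute breadth 0 to level means but
are reported as absent per data set.

`validate_against_patterns` evaluates the four qualitative claims (P1–P4
in its documentation) with seeded bootstrap confidence intervals rather
than fixed effect sizes, because an independent engine cannot match any
third-party program's numeric frequencies.  Two equalities hold only to
the optimizer's epsilon and are asserted with that tolerance: two runs
that find the same topology optimize it to log-likelihoods equal within
`epsilon`, and on plateau-dominated subsets the mean $Q_3$ log-likelihood
equals the mean $Q_1$ log-likelihood within `epsilon` rather than
strictly exceeding it.

## Problem sizes and their rationale

The shipped experiment sizes — 100 data sets of 16 taxa for the two-run
study, 3 × 12 data sets for the ladder, 20 replicates of 8 taxa × 50,000
sites for the consistency-limit check, 50 seeded climbs against the
6-taxon exhaustive oracle — were chosen as the smallest designs at which
each pattern is statistically decidable (bootstrap p-values and CI
overlaps stabilize near these sizes) while a full reproduction remains a
minutes-scale, single-CPU computation.  Larger designs sharpen the same
conclusions; they do not change them.

## Known limitations

* Irreproducibility here is dominated by likelihood plateaus (splits with
  no supporting sites tie exactly after branch-length collapse), with a
  minority of genuine multiple-optima cases; at hundreds of taxa the
  balance shifts toward search-limited irreproducibility, which this
  desk-scale engine reproduces only in miniature.
* The engine is single-threaded by design; determinism is part of its
  contract.
* Ambiguous bases and gaps are marginalized as fully unknown states;
  IUPAC partial ambiguity is not resolved (simulated data contain none).
* User-supplied alignments are supported through `read_alignment` plus a
  reference tree in Newick, but support-based reference-tree pruning and
  model selection are out of scope: the user must supply the reference
  tree and model.
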