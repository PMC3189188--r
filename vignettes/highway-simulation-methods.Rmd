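---
title: "Highways of gene sharing: simulation design, supertree scoring, and network construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Highways of gene sharing: simulation design, supertree scoring, and network construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the scientific choices behind `phyloweave`: the
simulation model, the reconstruction and supertree machinery, the conflict
screen, the network builder, and the numerical conventions that make every
run reproducible. It states no empirical result beyond what the package's
tests and `scripts/acceptance.R` themselves compute.

## The question the toolkit addresses

Concatenation (supermatrix) and supertree methods both pool signal across
gene families to beat stochastic error. They respond very differently to a
*highway of gene sharing*: many families transferred along one directed
donor → recipient route. Transferred families do not contribute random
noise — they carry a second, coherent phylogenetic signal. A supermatrix
averages the two signals inside one distance (or likelihood) estimate and
can switch allegiance wholesale; a quartet-based supertree keeps families
separate until the topology-voting stage, so the vertical plurality can win
as long as it remains a plurality. `phyloweave` quantifies where each
approach breaks as the transferred fraction *h* grows.

## Simulation model

**Species tree.** The default experiment uses the unrooted 7-taxon tree
`((A,(B,B')),C,(D,(E,F)))` with donor B' sister to B and recipient F in a
cherry with E. The internal branch subtending (E,F) has length *b*
(0.05 or 0.01 substitutions/site) — the branch whose recovery the
experiment probes. The remaining branch lengths are not dictated by the
experimental design, so the package fixes them at a single default of 0.1
substitutions/site, a moderate divergence typical of single-protein
phylogenies; the value is a visible `other_length` argument of
`default_species_tree()` and is recorded in every serialized config. The
"correct tree" for scoring is this tree restricted to A–F, because the
donor genome is excluded from all reconstructions.

**Sequence evolution.** Families are simulated as independent, identically
distributed site processes under the empirical JTT amino-acid model: root
states drawn from the JTT equilibrium frequencies, then per-branch
transitions `P(t) = exp(Qt)` with `Q` scaled so one unit of branch length
equals one expected substitution per site. The JTT exchangeability counts
and frequencies are embedded verbatim in the package and cross-checked
against an independent copy in the test suite. There are no indels: the
output is positional and is never realigned, so alignment artifacts cannot
leak into the comparison. The default simulation uses no among-site rate
variation and no invariant sites — the simplest process consistent with the
experiment — though `substitution_model()` supports a discrete gamma
(`gamma_k`, `gamma_alpha`) and `p_inv` for likelihood work; with invariant
sites the variable-site rates are rescaled by 1/(1 − p_inv) so the mean
rate stays 1 (the usual +I convention).

**The highway.** `apply_highway(gs, donor, recipient, h)` picks
`round(G·h)` families uniformly without replacement and overwrites the
recipient's row with the donor's extant sequence — transfer as
instantaneous ortholog replacement at the tips, which is the designed
protocol of the experiment (not a mid-branch transfer model). Provenance
flags record which families were touched.

**Scale and replication.** The headline experiment is 100 families × 300
residues × 100 replicates per HGT grid point (grid 0–60% in 5-point
steps), run for both *b* values by `scripts/acceptance.R`; the in-suite
acceptance checks run the identical pipeline at 25 replicates on trimmed
grids, which keeps the default `testthat` run to a few minutes while
leaving the majority thresholds statistically stable (the checked
frequencies sit near 0 or 1 at the asserted grid points). Every replicate
draws its RNG stream from `(master seed, grid index, replicate index)`, so
sweeps are byte-identical across reruns and grid points are independent.

## Reconstruction

**Distances.** Observed difference proportions use pairwise deletion of
gaps/ambiguities; the Kimura protein correction
`d = −ln(1 − p − 0.2 p²)` is applied up to its saturation point `p ≤ 0.85`,
beyond which the package raises an error rather than switching to lookup
tables — simulated data here never approach saturation, and an explicit
error is more honest than an extrapolation. `d(p)` is strictly increasing
and convex with `d(0) = 0` (property-tested).

**Neighbor joining.** The Saitou–Nei agglomeration is implemented with two
deterministic conventions, both property-tested: Q-criterion ties break by
the smallest (row, column) pair under the input taxon ordering, and a
negative estimated pendant length is clamped to zero with the deficit moved
to its sister branch so their sum (the joined distance) is preserved. NJ is
exact on additive matrices — topology and branch lengths — up to the n = 8
cases in the tests, and agrees with an independent implementation there.

**Likelihood.** `felsenstein_loglik` implements pruning with per-column
scaling; `exhaustive_ml_tree` enumerates all unrooted topologies (≤ 8 taxa)
and optimises branch lengths by cyclic Brent sweeps (bounds 10⁻⁸–10,
relative tolerance 10⁻⁶, max 50 sweeps). ML is provided for parity and for
small verification studies; the headline sweeps are NJ-driven, which keeps
the experiment fast and deterministic.

## Quartet supertrees

Each gene tree contributes, for every 4-taxon subset it covers, the induced
quartet topology; star restrictions count as abstentions. Per subset the
plurality topology and its *margin* (top weight minus runner-up) are
recorded; exact ties are undecided and impose no constraint. A candidate
supertree's score is the summed margin of the plurality quartets it
satisfies. For ≤ 8 taxa the search is exhaustive over all resolved
unrooted topologies (105 at the experiment's 6 reconstruction taxa), so
the reported supertree is exactly optimal under this declared scoring; ties
break deterministically by canonical newick order. The greedy mode is
quartet joining — repeatedly merge the cluster pair with the highest summed
cherry support, rescoring after each merge — and is regression-tested to
equal the exhaustive optimum across a battery of random 6–7-taxon
plurality maps. Margin weighting is the design choice that gives the
supertree its robustness: a handful of narrowly-won conflicting quartets
cannot outvote broadly-supported vertical signal. No bootstrap filtering of
embedded quartets is applied by default (a minimum-margin threshold is
available in `plurality_quartet_map` consumers).

## Conflict screen

`screen_conflicts` compares, for every pair of gene trees, the nontrivial
bipartitions with support ≥ *s* after restriction to the shared taxa, using
the standard four-intersection compatibility criterion; pairs sharing fewer
than 4 taxa are uninformative by convention. "Highly supported" has no
universal definition, so the threshold defaults to *s* = 0.9 and is
recorded in the report. Each conflict is rank-classified by a declared,
deterministic rule: the displaced taxa are those whose side membership
differs between the two (orientation-aligned) bipartitions, and each is
compared with the non-displaced taxa on its smaller ("conflicted-area")
sides — a different domain anywhere makes the conflict inter-domain, a
different order inter-order, otherwise intra-order. The rule is symmetric
in the two trees. Exclusion (`filter_partitions`) gap-masks the offending
taxa's sequences in the involved partitions rather than deleting rows, so
the supermatrix taxon set stays constant; intra-order conflicts are
preserved by default.

## Network construction

The scaffold is built from concatenated partitions as a
partition-length-weighted average of per-partition corrected distances
(Kimura for proteins, K2P for nucleotides), reconstructed with NJ and
rooted on the outgroup edge; the returned scaffold is canonicalised so its
postorder edge ids are stable across runs. Reticulation detection is
deliberately *not* a full duplication–transfer–loss reconciliation: no cost
scheme is specified for one, and an unverifiable optimisation would be
worse than a checkable rule. Instead, a gene tree that conflicts with the
restricted scaffold in a supported bipartition is reduced to its maximum
agreement subset (exact search ≤ 16 shared taxa, greedy leaf removal
beyond); the complement — the displaced taxa — is grouped into maximal
gene-tree clades, and each clade becomes a candidate reticulation from the
scaffold position of its gene-tree sister group (source) to its own
scaffold position (target). The displaced clade is always recorded as the
recipient; this polarity is an annotation, not a biological truth claim,
since donor and recipient are often not distinguishable from topology
alone. Candidates identical in (source, target, moved set) merge across
families; a reticulation is kept when at least `min_family_support`
families (default 5) back it, a noise floor that a single aberrant gene
tree cannot cross. How much evidence justifies calling an edge
"horizontal" in real data is a judgement the package leaves to its user —
the threshold is config, not a default biological claim. Networks serialise
as extended newick (each reticulation once as a labelled `#H` node at its
target, once as a `#H` leaf grafted into the source edge) plus an edge-list
TSV that round-trips through `read_network`.

## Numerical conventions and degenerate inputs

* Canonical newick: children ordered by smallest descendant label, unrooted
  trees written from the node adjacent to the smallest leaf, branch lengths
  at 6 decimals — string equality is topology equality, which the tests
  exploit throughout.
* Support values on 0–1 and 0–100 scales are both accepted and normalised
  to 0–1 internally.
* Fewer than 4 taxa: no nontrivial bipartitions, quartet machinery
  undefined, conflicts unevaluable, reticulation detection skipped with a
  logged reason.
* Star trees: empty bipartition sets; quartets unresolved; a
  zero-information alignment gives the deterministic canonical-order winner
  in exhaustive searches.
* All stochastic functions consume R's RNG; orchestration functions manage
  seeds explicitly so parallel or partial reruns reproduce byte-identically.

## What the generator does and does not emulate

The simulator produces equal-length, single-copy, gapless, perfectly
aligned families on one fixed species tree, with transfer as whole-gene
tip replacement along a single highway. Real data add indels and alignment
error, gene duplication and loss, rate heterogeneity among sites and
lineages, compositional heterogeneity, incomplete taxon sampling, and
transfers scattered over many routes and depths. Passing the package's
tests therefore demonstrates the behaviour of the *methods* under a clean,
controlled HGT signal — the regime where the supermatrix/supertree contrast
is interpretable — not the expected accuracy of either method on empirical
genomes. The conflict screen's published multi-domain application likewise
requires curated ribosomal alignments that are not shipped here; the screen
is validated on synthetic fixtures with a known taxonomy instead.

## Known limitations

* Exhaustive supertree and ML searches cap at 8 taxa; the greedy modes are
  heuristics beyond that.
* The quartet supertree scoring (margin-weighted satisfied pluralities) is
  a declared stand-in for unspecified legacy supertree software internals;
  it is exact and reproducible, but not a reimplementation of any
  particular historical program.
* Reticulation detection reports topological displacement, not
  reconciliation-optimal transfer scenarios, and records polarity only as
  annotation.
* The Kimura correction refuses saturated distances (p > 0.85) rather than
  approximating them.
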