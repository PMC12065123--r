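---
title: "Dependency-aware morphological parsimony with depclad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dependency-aware morphological parsimony with depclad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depclad)
```

## The problem: inapplicable characters

Morphological matrices are built on an encaptic (hierarchical) view of
anatomy: a structure carries substructures and properties, and a
character describing a substructure is only meaningful when the
structure itself is present. A matrix therefore contains *ontological
dependencies*: a hierarchically higher character (HHC) such as "tail:
absent/present" controls the applicability of dependents such as "tail
colour". When the controller is in a disabling state the dependent cell
is *inapplicable* (`-`), which is conceptually different from *missing*
(`?`) even though most parsimony software treats both as full ambiguity.

That conflation is not neutral. With inapplicables read as missing, the
optimizer happily reconstructs colours for ancestors that have no tail,
and those phantom reconstructions can change the relative score of
topologies that are otherwise equally supported. `maddison_fixture()`
reproduces the canonical demonstration: eight taxa, a tail controller
and a colour dependent, and two candidate topologies that both imply two
independent origins of the tail and differ only in the internal
arrangement of a mixed-colour tailed clade.

```{r maddison}
fx <- maddison_fixture()
comp <- build_composite(1:2, fx$matrix, fx$graph)
c(composite_A = sankoff_cost(fx$topologies[[1]], comp),
  composite_B = sankoff_cost(fx$topologies[[2]], comp))
sc_missing <- make_scorer(fx$matrix)   # inapplicable-as-missing
c(missing_A = sc_missing$total(fx$topologies[[1]]),
  missing_B = sc_missing$total(fx$topologies[[2]]))
```

Composite scoring ties the two hypotheses (for *every* assignment of
colours to the tailed taxa — the test suite asserts all sixteen);
the traditional treatment separates them on phantom colour steps alone.

## The composite-character model

`depclad` resolves dependencies by recoding. Each connected complex of
the dependency graph (links parsed from statement annotations such as
`[12.1>this]`, plus manually supplied single-state links and
serial-homologue blocks) is flattened into one *composite character*:

* its **states** are all dependency-consistent tuples of member states,
  where a dependent entry is inapplicable exactly when some controller
  entry is non-enabling (`enumerate_states()`);
* its **step matrix** charges, between two tuples, the weight of every
  member that differs *and is applicable on both sides*. Members
  inapplicable on either side are free: the controller's own change
  carries the cost of gaining or losing the whole dependent complex, so
  instantiating a dependent state at gain costs nothing extra. This
  free-instantiation rule is what makes two independent gains
  colour-neutral — the behaviour the recoding exists to provide;
* a **metric closure** (all-pairs shortest paths) is applied afterwards
  so that no direct transition is ever costed above an indirect route;
  the rule-based charges are metric in all cases we generate, but the
  closure makes Sankoff validity unconditional.

Trees are then scored by generalized (Sankoff) dynamic programming over
the tuple space for composites and by Fitch counting for independent
characters; both reduce to the same number on a degenerate one-member
complex.

### Serial homologues

Repeated body structures (e.g. limb exopods along a thoracopod series)
often transform jointly: one evolutionary step can switch several
serial positions at once. Scoring each position as an independent
character overestimates such homomorph transformations, increasingly so
for longer series. A `serial_block()` therefore discounts concurrency:
`m` members changing in the same transition cost
`w * (1 + (m - 1) * discount)` instead of `m * w`, with `discount`
defaulting to 1/10. Combined with ten-fold upweighting of all
characters (`weight = 10`), every cost stays integral in tenth-steps,
avoiding float ties. Blocks may additionally be `streak`-constrained:
tuples are restricted to contiguous runs of non-baseline states, which
excludes disrupted ancestral distribution patterns and shrinks the
state space (a run-length lattice of `n(n+1)/2 + 1` states for a binary
block of length `n`).

## Homoplasy and implied weighting

For every scoring unit the tree-independent minimum cost is computed:
observed-state counts for unordered characters, and an exact Steiner
minimal connection cost over the observed tuples (Dreyfus–Wagner
dynamic programming, up to 10 terminals; a minimum-spanning-tree value
with homoplasy clamped at zero beyond that) for composites. Homoplasy
is `h = (steps - min) / w`, measured per unit weight so that the
ten-fold upweighting used with serial discounts does not distort the
implied-weighting curve.

Equal weighting (EW) minimizes total weighted steps. Implied weighting
(IW) minimizes the concave fit `sum h/(h+k)`; small `k` punishes
homoplastic characters harder. A composite of `n` members receives the
fit of its *averaged* homoplasy times the member count,
`n * hbar/(hbar + k)` with `hbar = h/n`. The per-member attribution
inside a complex is not recoverable from a single Sankoff total, so the
averaged form is an approximation — a deliberate design choice over the
alternative reading (fit of the summed homoplasy), which would let one
member's homoplasy saturate the whole complex's fit.

The automatic concavity constant ("sk") is derived from a maximum
weight ratio `N` (default 15): `k = h_max / (N - 1)` makes a
homoplasy-free character weigh exactly `N` times the most homoplastic
one. `h_max` is measured on the best equal-weights trees found in a
preliminary search; an explicit `k` can always be supplied instead.

```{r sk}
compute_sk(h_max = 14, N = 15)
```

## Tree search

`multistart_search()` runs seeded random-addition replicates, each
swapped to a local optimum (NNI, SPR or TBR neighbourhoods over an
unrooted adjacency representation), optionally perturbed by a parsimony
ratchet (25% of characters temporarily doubled in weight) and by drift
(a bounded random walk accepting rearrangements within a 2% relative
score tolerance — a simplified, seeded analogue of the classic drift
strategy). Search stops early when the best score has been hit
independently `hits_required` times. Ties are collected, and trees are
deduplicated under the identity of their *collapsed* topologies: an
internal branch collapses when every unit admits a most-parsimonious
reconstruction with equal states at its two ends (minimum branch length
zero). Binary representatives are stored so that every saved tree
rescans to exactly the reported score.

All stochastic elements derive from explicit integer seeds; identical
configurations replay identically.

### The tree-collection closure protocol

Analyses that differ only in weighting often sit in each other's
basins. Every analysis therefore deposits its trees in a shared,
deduplicated `tree_collection()`; a TBR round seeded from collection
members under the current scorer adds any tree scoring at least as well
as the collection's best, and the pipeline loops these TBR-only
cross-checks over all analyses until a full pass adds nothing. Because
a TBR neighbourhood is deterministic, each (analysis, tree) pair needs
checking only once; the collection memoizes this, which bounds the
closure loop's cost without changing its fixed point.

## The k-browsing pipeline

`run_pipeline()` executes, per dataset: EW, IW for a user list of k
values (default 1–25), and IW at sk; per analysis it saves the MPTs and
their strict consensus, updates the collection, and finally builds a
labelled normalized Robinson–Foulds (nRF) matrix over all distinct MPTs
(`RF / (2(n-3))`, the maximum for binary trees; full precision stored,
two decimals half-up for display). Congruence across the analytical
treatments is summarized by `select_congruent_mpts()`: the sk analyses
act as anchors, and from every other batch the tree(s) closest to any
anchor are kept and combined into a strict consensus — a way of
drawing a defensible summary from a heterogeneous MPT pool.

Bootstrap support resamples *scoring units* (independent characters,
and whole complexes when composites are active) with replacement,
searching each pseudo-replicate with a reduced configuration. Whole
complexes are the resampling unit because the fit total is a sum over
units; resampling raw columns would break controller–dependent pairs
and manufacture matrices no consistent scorer could produce. Default
replicate counts are 1500 (traditional) and 100 (composite); the
bootstrap is off by default in `pipeline_config()` because it dominates
runtime.

## The synthetic-data generator

`simulate_matrix()` produces matrices with the structure the method
assumes: characters evolved on a known tree, dependency complexes
(binary controllers gating dependents of 2–4 states), optional serial
blocks evolving as moving streaks, and uniformly injected missing data
(default 12.85% of applicable cells, with an optional per-taxon skew
for unevenly known taxa). Dependent characters change only on branches
where their controller is present, so generated matrices are
dependency-consistent by construction; the truth ledger records the
tree, exact per-character change counts and complex membership, giving
tests exact oracles.

Changes follow a fixed-number-of-changes model: each character receives
exactly `state_change_rate` changes (fractional remainders as a
Bernoulli top-up) placed on random branches. The alternative — drawing
Poisson counts — makes ledgers no less exact but concentrates so much
homoplasy in a minority of characters that, at one expected change per
character, most-parsimonious trees shorter than the generating tree are
common; under the fixed-count model parsimony recovers the generating
tree reliably at that rate, which is the regime the validation
experiments use (8–12 taxa, ~6 characters per taxon, 10 seeds).

What the generator does *not* emulate: correlated homoplasy
(convergence concentrated in anatomical modules), taxon-dependent
character applicability beyond the dependency rules, multi-level
dependency chains (complexes are controller-plus-dependents stars), or
any realistic anatomy. Passing tests show the machinery is correct
under the stated model, not that any empirical matrix meets it.

## Numerical choices and limitations

* Scores are compared with an absolute tolerance of 1e-9; serial
  discounts keep costs on a tenth-step lattice so ties are exact.
* Composite state spaces are capped (default 4096 tuples) with an
  error advising a complex split, never silently approximated.
* Tie-breaking in search is deterministic: first-best in a fixed edge
  enumeration order; MPT sets are therefore reproducible per seed.
* Validation problem sizes: exhaustive-search oracles at 5–7 taxa (105
  and 945 topologies), brute-force ancestral enumeration at up to 6
  taxa and 4 states, pipeline checks at 6–8 taxa. These sizes make the
  oracles exact while keeping the full suite fast.
* The composite cost semantics here are defined by this package's
  rules (free dependent instantiation, concurrency discount, metric
  closure). Other implementations of dependency-aware parsimony make
  their own accounting choices — e.g. for nonhomology counting or for
  complexes with three or more hierarchy levels — and may legitimately
  report different absolute scores for the same data; comparisons
  across programs should be made on tree sets, not raw scores.
* IW across datasets with different weight scales is comparable only
  because homoplasy is normalized per unit weight; mixing weighted and
  unweighted copies of a dataset in one collection is still best done
  with EW scores as the tie-breaking reference.
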