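---
title: "Simulation-based prediction of protein complexes and their abundances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based prediction of protein complexes and their abundances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simcomplexome)
```

## The problem and the modelling idea

Graph-clustering methods predict which proteins form a complex but say
nothing about how many copies of the complex a cell contains, even though
complex formation is a dynamic, stochastic process in which low-abundance
subunits and competition for binding sites limit what can assemble.
`simcomplexome` instead *simulates* complex formation. Proteins are
discrete objects whose binding sites are their annotated domains; a bond
may form between two proteins only where a domain-domain interaction (DDI)
licenses it and a protein-protein interaction (PPI) supports it. Because a
domain slot can hold at most one bond at a time, abundant proteins
out-compete rare ones for shared partners, and the copy-number spectrum of
the proteome shapes both the composition and the quantity of the complexes
that emerge.

## The integrated binding model

`build_model()` merges five tables: a PPI edge list, a protein-to-domain
table (one row per slot occurrence), a DDI list, a protein abundance table
and a functional annotation table. DDI evidence is used only on protein
pairs that actually interact. PPI edges with no supporting domain pair are
*rescued* when the two proteins share a functional annotation term: a
fresh, edge-private pair of fictitious domains is appended to the two
proteins and licenses exactly that edge. Giving every rescued edge its own
domain pair (rather than a shared promiscuous domain) guarantees that
fictitious rules can never create binding between protein pairs the PPI
network does not support. Edges that are neither DDI-covered nor rescued
are dropped, and the model records the coverage fraction before and after
rescue. A protein is retained only if it participates in at least one rule
and has abundance data; a protein whose only slots are fictitious is
retained, and each complex later reports the fraction of its bonds that
rest on fictitious domains so that predictions grounded in known DDIs can
be recognized.

Instance counts are the square root of raw copies per cell, rounded
half-up with a floor of one for any protein present. The square root keeps
proteome-scale simulations tractable while preserving abundance ranks;
predicted complex counts are squared on output to restore the original
scale, so the reported abundance of a complex counted `k` times is `k^2`.

## The lattice simulation

`run_simulation()` executes an operator-splitting (Gillespie
multiparticle) scheme on a square lattice of sub-volumes:

* **Diffusion.** Once per interval, every connected bound group - and
  every free instance - independently either stays or moves into one of
  its valid 4-neighbour sub-volumes, chosen uniformly; at a reflecting
  boundary the choice is resampled among the valid options (periodic
  boundaries are available as a flag). Bound groups move as rigid units,
  which is the simplest rule that preserves the invariant that all members
  of a bound group are co-located; per-member moves with bond-stretch
  rejection were considered and rejected as needless complexity.
* **Reaction.** Within each sub-volume, an exact stochastic simulation
  runs for the interval duration. Every pair of free, co-located,
  complementary slots is an association channel with propensity `k_on`;
  every existing bond is a dissociation channel with propensity `k_off`.
  Site exclusivity is structural: a slot engaged in a bond contributes to
  no association channel. Dissociation does not relocate the fragments, so
  freshly separated sub-complexes may immediately rebind - closely located
  proteins should have a higher chance to bind.

Defaults: `k_on = 1`, `k_off = 0.1` in arbitrary time units, a
binding-favoured regime in which complexes accumulate; the rates are not
identifiable from the input data and are fully configurable (per-rule
overrides are used for drugs). The grid defaults to
`ceiling(sqrt(total_instances / 50))` sub-volumes per side, targeting
roughly 50 instances per sub-volume - fine enough that distant instances
rarely meet, coarse enough that every instance can traverse the lattice
within the simulated span. A run lasts `t_end = 200` diffusion intervals;
complexes are collected at the midpoint and the end of each of two
independent runs with different random initial placements, giving four
collection points in total. More runs mostly add rarely-formed complexes
of low confidence, so two is the default rather than the maximum the
hardware allows. All randomness derives from the base seed (run `r` uses
`seed + r - 1`), and identical inputs reproduce identical trajectories
exactly.

At each collection point, every connected bound group with at least two
members becomes one *simulated complex* (SC) carrying its member multiset,
bond list and fictitious-bond fraction.

## From simulated to refined complexes

Many SCs are near-duplicates of one another. `build_frequency_matrix()`
counts, for every unordered protein pair, the number of SCs containing
both proteins. The count is normalized to an affinity

```
affinity(a, b) = count(a, b) / max(occurrence(a), occurrence(b))
```

and proteins are clustered by average-linkage agglomeration on `1 -
affinity`, cutting the dendrogram at `1 - tau` with `tau = 0.5`: two
proteins cluster together roughly when they co-occur in at least half of
the SCs of the more frequent one. Max-normalization plus average linkage
was chosen because it is deterministic, recovers block structure exactly
on noiseless input, and penalizes promiscuous proteins that occur in many
contexts; the clustering sits behind a single function boundary and can be
replaced wholesale. Proteins are processed in lexicographic order, so ties
resolve identically on every run.

Each SC is then assigned to the refined complex (RC) it overlaps best,
provided the overlap score reaches `assoc_threshold = 0.25` - the same
0.25 convention used for benchmark matching - with ties going to the
larger RC and then the earlier-numbered one. The number of assigned SCs is
the RC's simulated abundance; the reported abundance is its square. Counts
are also kept per run (for the coefficient of variation, `sd/mean` across
runs, recorded as missing when the mean is zero) and per collection point
(the replicate unit of the perturbation t-test). Filtering with
`filter_policy()` drops low-abundance large complexes (`"LG"`) or
low-abundance small complexes (`"SM"`); the default thresholds (simulated
abundance below 2; size boundary 10) are package choices, applied to the
pre-squaring count because that is the quantity the simulation actually
produced. Squaring happens at reporting, after filtering.

## Benchmark scoring

All comparisons use the overlap score `omega(A, B) = |A n B|^2 / (|A| |B|)`.
A reference complex is *recalled* when some prediction exceeds
`omega > 0.25`; the *maximal matching ratio* is the total weight of an
exact maximum-weight one-to-one matching between reference and predicted
complexes divided by the reference count; the *geometric accuracy* is
`sqrt(Sn * PPV)` over the reference-by-prediction intersection-count
matrix; their sum is the *composite score* in [0, 3]. An alternative
f-score (complex-level harmonic mean of precision and recall at the same
threshold) is provided because the two systems penalize wrong large and
wrong small complexes differently. A prediction whose best overlap is at
or below 0.25 is labelled a newly predicted complex - the boundary counts
as new. Reference sets are preprocessed by dropping complexes smaller than
three members and greedily removing complexes that overlap an already-kept
complex at 0.8 or more, scanning in descending size order so the result is
input-order invariant. SC member multisets are collapsed to sets before
scoring, since reference sets carry no stoichiometry.

## Drug perturbation

A drug is modelled as one more species. Its bound domains are inferred by
a one-sided hypergeometric enrichment of each domain among the drug's
target proteins versus all model proteins, Benjamini-Hochberg adjusted at
`alpha = 0.05`; fictitious domains are excluded as candidates because they
are bookkeeping constructs, not physical binding surfaces. If nothing is
enriched, the fallback takes domains carried by more than half of the
targets and says so. The drug gets one slot per bound domain and binding
rules against every carrier of that domain that is a target or a PPI
neighbour of one, with configurable (default: protein-like) kinetics. Drug
instances then compete for those slots under the same exclusivity rule,
occluding protein-protein bonds.

Control and treated complexomes are simulated under identical seeds,
refined (drug instances are removed from treated complexes first, and any
complex held together only by the drug is split into its remaining
fragments), and matched one-to-one greedily by descending overlap above
0.25. Matched pairs are tested with a Welch t-test on per-collection-point
abundances (two runs x two time points = four replicates per condition by
default); `p < 0.05` calls a quantitative change, and complexes without a
best match on the other side are called qualitatively altered. Two
identical constant replicate vectors give `p = 1` by convention, so a
zero-abundance drug - which leaves the simulated trajectory bit-for-bit
identical - yields an all-unchanged call set.

## What the synthetic fixtures emulate

`generate_fixture()` builds a self-consistent input bundle around planted
ground-truth complexes: each planted complex is a connected graph (random
spanning tree plus extra edges at probability 0.3) whose every edge has
its own exclusive domain pair; a configurable fraction of those pairs
(default 0.7) is written to the DDI table, the rest exercising the
fictitious-rescue path through a complex-wide shared function term. Decoy
proteins (default 100) and spurious edges (default 5% of the PPI) provide
background, and raw abundances are log-normal (`meanlog = 4`, `sdlog = 1`,
clamped at 1), spanning roughly 10 to 1e5 copies like a proteome-wide
abundance table. The planted member sets double as the reference set, so
recall against them has an exact ground truth.

`generate_drug_fixture()` rewires one planted complex through a single
bridging domain carried twice by every member and nowhere else - the
enrichable signal for drug-domain inference - and doses the drug at an
instance count of 50 times the fixture's mean protein instance count.
That preserves the instance-scale excess a saturating inhibitor has when
dosed at the abundance of the most abundant protein in a real
proteome-wide dataset; the compact fixture's abundance spread is far too
narrow for the literal most-abundant-protein rule to produce an excess.

The fixtures deliberately do *not* emulate scale-free network topology,
overlapping or nested complexes (planted complexes are disjoint by
default), measured kinetic constants, three-dimensional geometry, or
membrane compartments. Tests passing on these fixtures therefore
demonstrate that the machinery is correct and that the designed signals
(abundance dependence, competition, drug occlusion) propagate through the
pipeline - not that real complexomes will be predicted at any particular
accuracy.

## Numerical and degenerate-case conventions

* Square-root instance counts round half-up (`floor(sqrt(x) + 0.5)`).
* Undirected edges, rules and domain pairs are deduplicated in canonical
  (lexicographic) orientation; fictitious domain names are minted by a
  deterministic counter over sorted edge order, so model building is
  reproducible byte for byte. Self-interactions are accepted and bind
  distinct slot occurrences.
* The dendrogram cut is inclusive: affinity exactly `tau` merges.
* The MMR matching is exact; greedy matching is used only for pairing two
  complexomes in perturbation calls, where a one-to-one best-first pairing
  is the stated procedure.
* Empty references make recall/MMR/accuracy undefined (`NA`), not zero;
  empty predictions score zero. An all-zero intersection matrix gives
  accuracy 0. A t-test with fewer than two replicates per arm is
  `untestable`.
* Simulation event selection guards against floating-point drift in the
  cumulative propensity walk; conservation, site exclusivity and
  co-location are structural invariants of the state representation, and
  the test suite re-derives them from raw snapshots.

## Problem sizes used by the test suite

The shipped tests run the full pipeline on the default fixture (10 planted
complexes of 3-8 members, 100 decoys, about 500 protein instances on a 4x4
lattice, 200 diffusion intervals), which completes in about a second per
run; kinetic and competition checks use dedicated micro-models (one or
three proteins in a single sub-volume) with dense sampling, and the
abundance-sensitivity comparison samples ten collection points per run to
estimate mean complex abundance with enough precision for a paired
comparison across five seeds. These sizes are the package's validation
design: large enough for every mechanism to express, small enough to run
anywhere.

## Known limitations

Kinetic rates, lattice resolution and simulated duration are not
identifiable from the input tables; predictions should be read as
relative, not absolute, quantities unless the rates are calibrated
externally. Rigid-unit diffusion ignores complex geometry and excluded
volume. The clustering refinement is one defensible choice among several;
alternative refiners can be swapped in behind `cluster_matrix()`. Variant
RCs matching one reference complex are reported separately (their overlap
structure is available via `rc_overlap_graph()`) and are not merged into
consensus complexes.
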