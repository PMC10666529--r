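---
title: "Temporal molecular graphs for transformation prediction in complex mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal molecular graphs for transformation prediction in complex mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ultrahigh resolution mass spectrometry of dissolved organic matter (DOM)
resolves thousands of molecular formulas per sample, but a time series of
such measurements only shows *net* intensity changes per formula. Which
chemical transformations — decarboxylation, dehydration, oxidation — moved
intensity from educts to products between two sampling points is not
directly observable. `domgraph` models a time-resolved formula table as a
snapshot-based temporal property graph and predicts likely transformations
by combining two independent signals: the formula arithmetic of a fixed set
of transformation units, and the simultaneous loss of educt intensity and
gain of product intensity across a transition.

```{r setup}
library(domgraph)
```

## The temporal graph model

Each detected formula at each snapshot is one *Molecule* node, uniquely
identified by the (formula, snapshot) pair and carrying its normalized peak
intensity. Snapshots are consecutive integers `1..n`; they may represent
non-equidistant wall-clock times or cumulative irradiation doses — that
metadata rides along for reporting and never enters the algorithms. `n`
snapshots always define exactly `n - 1` transitions, and every edge spans
exactly one transition; no edge connects nodes inside one snapshot.

Three edge types connect the snapshots:

* **SAME_AS** links the same formula in consecutive snapshots and carries
  the intensity trend, the ratio of later to earlier intensity.
* **POTENTIAL_TRANSFORMATION** links a formula at `t` to the formula at
  `t + 1` obtained by adding a transformation unit's elemental delta,
  whenever that product formula was detected at `t + 1`. Matching is by
  exact integer element counts, never by mass tolerance: upstream formula
  assignment is taken as given. Several units between the same node pair
  give several parallel edges, and unit-level counts (shares, importance)
  count those separately.
* **PREDICTED_TRANSFORMATION** is the subset of potential edges selected by
  the prediction algorithm below.

A zero or missing intensity means "not detected": no node is created.
Negative intensities are a hard error rather than being clamped.

### Pruning isolated molecules

After potential edges are computed, molecules that take part in no
potential transformation anywhere are omitted together with their whole
intensity series, and the omitted fraction is reported. Pruning is defined
at the molecule (formula) level deliberately: a molecule that reacts on one
transition keeps *all* its snapshots, so the intensity trends the
prediction step needs remain available even on snapshots where that
molecule has no transformation edge of its own. (Pruning per individual
(formula, snapshot) node would silently delete the SAME_AS partners of
reacting nodes and starve the predictor of trends.) Pruning runs once,
after edge computation and before prediction, and is idempotent.

## Transformation units

A transformation unit is a named, signed elemental delta, e.g. `-CO2` with
`dC = -1, dO = -2`. Units are grouped by the sign of their monoisotopic
mass delta into *photo eliminations* (mass loss) and *photo additions*
(mass gain). Direction is part of the unit: a pair explained by `+CO2` is
only matched if the table contains `+CO2`; reverses are never generated
automatically.

The shipped default (`default_units()`, 22 entries) is a synthetic
compilation of transformation units commonly reported for DOM
photochemistry: eliminations of small stable fragments (CO2, CO, H2O, H2,
CH2, CH2O, HCOOH, ketene, acetic acid, CH4, SO3, H2SO4, NH3, reverse
nitration) and the additions driving photo-oxidation (+O, +O2, -H2+O,
hydrogenation, hydration, nitration +NO2-H, oxidative deamination +O-NH).
The unit set is an *input* of the method: replace it with a lab-specific
table via `load_units()` (columns `name,dC,dH,dN,dO,dS[,dP]`).

Formulas live over a fixed element set, CHNOS by default with optional P.
Monoisotopic masses come from one IUPAC constants table stored to more than
six decimals. Molecular descriptors follow the community-standard
definitions: DBE `1 + C - H/2 + N/2`, the modified aromaticity index
(`0.5·O` variant, with the plain variant also reported) defined as 0 when
its denominator is non-positive so descriptor tables never contain
undefined entries, and the nominal oxidation state of carbon
`4 - (4C + H - 3N - 2O - 2S)/C`.

## The transformation prediction algorithm

An edge `A@t -> B@t+1` is predicted if and only if A's intensity trend over
the transition is *decreasing* and B's is *increasing*, both beyond the
measurement error margin `m` (default 0.05, i.e. 5 %). The margin is
applied to the intensity *ratio* because the trend itself is defined as a
ratio: trends strictly below `1 - m` are decreasing, strictly above
`1 + m` increasing, and the closed band in between — boundaries included —
is consistent. A change must exceed the error margin before it is acted
upon.

The predicate is edge-local, so the result does not depend on whether one
iterates over products or educts, or in which order — the suite asserts
this by shuffling input row order.

### Appearing and disappearing molecules

Formulas that appear or vanish between snapshots have no SAME_AS edge on
that transition, so the predicate as stated cannot fire. Two policies are
offered:

* `strict` (default): both SAME_AS trends are required. This is the literal
  reading of the predicate and never extrapolates missing intensities.
* `zero_fill`: a product absent at `t` counts as increasing and an educt
  absent at `t + 1` as decreasing, so newly formed (transient) compounds
  and fully consumed educts can take part.

The choice is a configuration flag and is recorded in every run report.

### Edge weights

Each predicted edge is weighted by equal apportionment of the educt's loss
over its outgoing predicted edges and the product's gain over its incoming
predicted edges on that transition:

    weight(A@t -> B@t+1) = 1/2 * ( loss_A / outdeg(A, t)
                                 + gain_B / indeg(B, t+1) )

with `loss_A = I_A(t) - I_A(t+1)` (all of `I_A(t)` for a disappearing educt
under `zero_fill`) and `gain_B = I_B(t+1) - I_B(t)` (all of `I_B(t+1)` for
a new product). This scheme uses exactly the ingredients available on the
graph — trends and node intensities — is symmetric in educt and product,
and obeys a conservation law the tests assert to 1e-12 relative: per
transition the weights sum to half the total participating loss plus gain.
Unit *importance* is then the unit's weight sum normalized by the
transition total.

## The light graph and clustering

The light representation has one node per unique formula (with its full
intensity series) and one edge per ordered formula pair, aggregating every
per-transition record `{transition, unit, predicted, weight}`. The
conversion is lossless in both directions — `from_light(to_light(g))`
reproduces the graph exactly, which the suite checks structurally on
random graphs.

Clustering uses weighted label propagation on the light graph. The
clustering weight of a formula pair is the *number of predicted records*
between the two molecules, summed over both directions and all
transitions; edges are treated as undirected for community structure (a
switchable choice — reaction direction is not meaningful for "reacts
together" grouping). The update is asynchronous: each node starts with a
unique label and, visiting nodes in a seed-shuffled order each sweep,
adopts the label with the largest incident weight sum, ties broken by the
smallest label. Iteration stops when a sweep changes nothing (converged
assignments are exact fixed points) or after `max_iter` sweeps (default
100; non-convergence returns the current assignment with a warning).
Determinism given the seed is a hard contract needed for testability; the
global RNG stream is left untouched. Pairs connected only by unpredicted
potential records have weight zero and such nodes end as singletons unless
zero-weight adoption is explicitly enabled.

## Analytics

* `transition_stats()`: node counts per snapshot, SAME_AS counts
  partitioned into increasing/decreasing/consistent, potential and
  predicted counts, and mean predicted edges per molecule (predicted count
  over the node count at the transition start).
* `unit_shares()`: per transition, each unit's share of predicted edges
  over the full unit table (zeros kept, so shares sum to 1); per unit the
  average share, and the relative change in share from the first to the
  last transition. Shares are defined per transition, so "first to last
  snapshot" is implemented as first-to-last transition carrying predicted
  edges; a unit absent from the first transition has its relative change
  flagged undefined rather than divided by zero.
* `unit_group_shares()`: the photo addition vs photo elimination roll-up of
  the share matrix.
* `weighted_descriptors()`: per snapshot, intensity-weighted means of MW,
  H/C, O/C, DBE, AImod, NOSC.
* `cluster_report()`: cluster sizes, element-class composition, descriptor
  means, within-cluster unit shares, and the mean intensity trend pooled
  over the educt and product trends of the cluster's predicted edges.
  Within-cluster shares count only records whose educt *and* product lie in
  the cluster; records crossing cluster boundaries are counted separately
  rather than attributed to either side. On symmetric dynamics (losses
  mirrored by gains) the pooled mean trend is 1 exactly, and in practice it
  stays close to 1 because every cluster contains both educts and products.

## The synthetic-data generator

`simulate_snapshots()` exists so that every stage is testable without an
external data set. It emulates a photodegradation time series: seed
formulas sampled over realistic CHNOS ranges (C 12–30, H/C 0.8–1.8, O
3–14, occasional N and S), log-uniform initial intensities spanning one
decade, first-order transfer kinetics — per transition each active
(formula, unit) pair moves the fraction `1 - exp(-rate × dose)` of the
educt's intensity to the product — per-transition dose multipliers
(including dose-0 dark transitions), an optional mineralization sink (off
by default so intensity totals are conserved exactly), and multiplicative
log-normal measurement noise, because the prediction margin is
ratio-based. Products are pre-seeded at a small fraction (default 5 %) of
their educt's initial intensity so both ends of a transformation exist on
every snapshot. By default only seed formulas act as educts
(`products_react = FALSE`), keeping every ground-truth record's educt
strictly decreasing and product strictly increasing, which is what makes
exact recovery statements possible.

What the generator does *not* emulate: real DOM assemblage chemistry,
isomer multiplicity, ionization and matrix effects, correlated noise, and
detection limits. Passing recovery tests therefore demonstrate
algorithmic correctness — the predictor finds exactly the planted
transformations under the stated conditions — not field performance on
real FT-ICR-MS data.

## Numerical and design choices

* Boundary trends equal to `1 ± m` are consistent (strict inequalities):
  acting requires exceeding the margin.
* The AImod denominator degenerate case maps to 0, documented above.
* Unit tables are validated fail-fast: duplicate names, duplicate delta
  vectors, all-zero or non-integer deltas are load errors with row
  numbers; infeasible unit applications (negative counts, carbon hitting
  zero) are values (`NA`), not errors, because infeasibility is routine
  during edge enumeration.
* Label propagation ties break to the smallest label; together with
  seed-shuffled visiting order this makes runs reproducible and converged
  states exact fixed points.
* Exported tables and scripts print doubles with 17 significant digits so
  that re-import is exact; the GraphML path goes through igraph and round
  trips to within write precision.
* Test and acceptance problem sizes: property suites use graphs of up to
  about 50 nodes over 4 snapshots (100 seeded replicates per property);
  the end-to-end acceptance run uses 120 seed formulas over 13 snapshots
  with varying dose and 10 % noise, and a noise-free 5-snapshot recovery
  control. These sizes exercise every code path while keeping the whole
  suite fast enough to run routinely.

## Known limitations

* Only net reactivity between consecutive snapshots is visible; multi-step
  paths within one transition and true kinetics are out of reach by
  construction.
* Transformation prediction is formula-level; isomers are indistinguishable
  and structural feasibility is not checked.
* The default unit table is a constructed compilation (see above); for
  publication-grade analyses supply the unit set appropriate to your
  chemistry.
* The weight formula is one defensible choice among several; it is defined
  by its conservation law rather than by a mechanistic derivation, and
  alternative schemes can be plugged in behind the same interface.
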