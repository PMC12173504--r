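---
title: "Order-dependent strategies in social dilemmas on higher-order networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Order-dependent strategies in social dilemmas on higher-order networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypercoop)
```

## The model

A population of `N` players occupies a two-layer hypergraph: a pairwise
layer `E_pair` of two-player games and a triangle layer `E_tri` of
three-player games. Every node takes part in `k_pair` pairwise edges and
`k_tri` triangles, so it plays `k_pair + k_tri` games in total. Each player
carries an order-dependent *strategy vector*: one cooperate/defect slot used
in pairwise games and a second, independent slot used in three-player games.
This reflects the empirical observation that people behave differently in
dyads and in groups; the uni-dimensional (scalar-strategy) population is
retained as a baseline (`mode = "scalar"`).

### Payoffs

The pairwise game is a prisoner's dilemma with temptation, reward,
punishment and sucker payoffs `T > R > P > S` (defaults 1.1, 1, 0, -0.1).
The three-player game is a 2 x 2 x 2 payoff cube. Its four *unanimous
partner* entries are tied to the pairwise game by a comparability
constraint: a triangle whose other two members play `x` pays the focal
player exactly what two pairwise games against `x` would,
`X_tri = 2 X_pair` for all four base entries. Two payoffs have no pairwise
counterpart:

* `G_tri` — each cooperator's payoff in a mixed group {C, C, D};
* `W_tri` — each defector's payoff in a mixed group {D, D, C}.

The dilemma strength is `alpha = W_tri - G_tri` with `W_tri = 0.7` held
fixed, so `make_scheme(alpha)` spans the whole family with one knob. For
`alpha > 0` (a *strong* dilemma) every Nash condition of the multiplayer
dilemma holds and full defection is the only equilibrium; for `alpha < 0`
(*relaxed*) a lone defector among two cooperators is a second equilibrium,
because the mixed-group switch condition `W_tri > G_tri` fails.
`classify_dilemma()` evaluates all eight inequalities and names any
violations; note that for `alpha < -1.3` the cooperator ranking
`R_tri >= G_tri` is violated as well (`G_tri = 0.7 - alpha` exceeds
`R_tri = 2`), which the report flags rather than forbids.

```{r payoffs, eval = FALSE}
scheme <- make_scheme(alpha = -0.5)
triple_payoffs("D", "C", "C", scheme)  # lone defector: 2.2, cooperators: 1.2
classify_dilemma(scheme)
```

### Structure and topological overlap

The two layers are coupled structurally through the overlap
`omega = |E_pair ∩ E_proj| / |E_pair|`, the fraction of pairwise edges that
are also projections of triangles. `build_full_overlap()` constructs the
`omega = 1` extreme — a three-regular simplicial complex — by
configuration-model stub matching: each node contributes `k_tri` stubs,
stubs are shuffled into triples, and the matching is redrawn whenever a
triple repeats a node, a triangle duplicates, two triangles share two nodes,
or a layer is disconnected (up to 1000 restarts; rejections are rare for
`N >= 100`). The pairwise layer is then *defined* as the triangle
projection, which fixes `k_pair = 2 k_tri` and `omega = 1` exactly.

Lower overlaps are produced by degree-preserving *criss-cross* rewiring:
draw two pairwise edges A–B and C–D with random endpoint orientation,
require the four nodes to be distinct with no other links among them,
replace the edges by A–D and B–C, and revert any swap that disconnects the
pairwise layer. A swap is committed only if it strictly reduces the number
of shared edges without undershooting `target - tolerance`; this never
overshoots, converges in a few thousand draws for `N = 300`, and leaves the
triangle layer bit-identical. Only decreasing rewiring (from the simplicial
starting point) is supported. The default tolerance is the one-edge
granularity `1 / |E_pair|`.

### Imitation dynamics

One elementary update: pick a uniform focal player `f` and a model `m`
uniform over `f`'s de-duplicated co-players across both layers (a
`layer_then_neighbour` alternative — layer with probability 1/2, then a
co-player within it — is available since the sampling convention is not
uniquely determined by the model description). Both players' payoffs are
summed fresh over *all* their games in both orders, and the Fermi
probability

```
Pi_t = 1 / (1 + exp(-w (pi_m - pi_f)))
```

with noise `w = 1 / (k_pair + k_tri)` (about 0.16 for the default degrees)
gates the imitation. The inter-order coupling `pswitch` then decides *which*
strategy is copied *where*: the focal updates one slot per elementary update
(target slot fair coin), and the source is the model's same-order slot with
probability `1 - pswitch` or its other-order slot with probability
`pswitch`. The five outcome probabilities (four copy events plus no change)
are exposed by `outcome_probabilities()` and sum to one; an update whose
source equals the target's current value counts as an accepted no-op. A
Monte Carlo step (MCS) is `2 N` elementary updates in vector mode (`N` in
scalar mode), so each player expects one update per slot per MCS.

The random-draw order is fixed and documented (focal, model [layer, then
neighbour under the layer rule], target slot, source order, acceptance), and
the compiled update loop consumes the same uniform stream as the pure-R
reference `elementary_update()`; the test suite asserts bit-identical
trajectories from a shared seed. Payoffs are recomputed from scratch at
every update — there is no caching to go stale.

### Quasi-stationary evolution

Both consensus configurations are absorbing, so stationary densities are
measured with the quasi-stationary method: evolve one MCS at a time; if the
state is absorbing, replace it by a previously visited active state sampled
with probability proportional to dwell weight (`qs_teleport()`), then
continue. Active states are recorded every `cadence` MCS (default: every
MCS, each snapshot carrying its dwell time) into a bounded reservoir of
`capacity` snapshots (default 100).

Two replacement policies are provided. The default, `memory = "recent"`,
always overwrites a uniformly chosen stored snapshot once the reservoir is
full, giving an exponentially forgetting sample with memory horizon of
roughly `capacity x cadence` MCS — the standard quasi-stationary simulation
practice, and necessary for the reservoir to forget the initial transient
within the run lengths used here. `memory = "full"` keeps classic reservoir
sampling (inclusion uniform over the entire visited history); it is provided
for sensitivity analysis, but with it teleports keep resampling the
transient and the stationary window never decontaminates, so it is not the
default.

Absorption is checked once per MCS (the observables are per-MCS quantities;
sub-MCS excursions through a homogeneous configuration are not observable at
that granularity). Two triggers are available: the default `either_layer`
declares the state absorbing as soon as *either* slot type is homogeneous —
the literal reading of "full cooperation or defection for either interaction
order" — while `joint` only triggers when no elementary update can change
the state (all `2N` slots equal when `pswitch > 0`; each layer homogeneous
separately at `pswitch = 0`). The choice matters at `pswitch = 0`: under
`either_layer` the dominated pairwise layer can never actually reach full
defection (it hovers just above it, around a 5% cooperator fraction at
`N = 300`), whereas under `joint` it absorbs exactly. The initial state
seeds the reservoir, so an absorption before the first record teleports back
to the start instead of failing.

## Experiments and study conditions

`experiment_config()` defaults encode the full-scale study conditions:
`N = 1500`, `k_pair = 4`, `k_tri = 2`, initial cooperator density 0.5 per
slot type placed as exact counts (not Bernoulli draws), `1e5` MCS with the
last `1e4` averaged as the stationary window, and `M = 400` independent
runs. The tests and the acceptance script run a scaled-down version —
`N = 300`, `2e4` MCS, window `2e3`, `M = 20` — chosen so a full ensemble
completes in about a minute on one core while keeping `N k_tri` divisible
by 3 and the degrees at their study values. Every run regenerates and
rewires its own structure from its own seed, so ensembles average over
structural as well as dynamical randomness; per-run seeds are spawned from
the master seed through a single `sample.int()` stream, making every result
byte-reproducible.

`exact_small_system_oracle()` is the package's independent check on the
dynamics: for systems with at most 12 strategy slots it enumerates all joint
configurations, builds the exact one-step transition matrix implied by the
update rule, and solves for absorption probabilities by linear algebra.
With an equal-payoff scheme the cooperator count is a martingale on
regular structures, so consensus probabilities equal the initial cooperator
fraction — a parameter-free correctness check — and simulated fixation
frequencies must match the chain within Monte Carlo error.

## What the scaled-down simulations show — and what they do not

At `pswitch = 0` the two layers are dynamically decoupled: the pairwise
prisoner's dilemma collapses to (near-)full defection while the relaxed
three-player game (`alpha = -0.5`) sustains high cooperation, giving an
overall density near one half — about 0.46 at `N = 300` in this package's
runs. The triangle layer's quasi-stationary cooperator fraction is
size-dependent: about 0.85 at `N = 300` versus about 0.97 at `N = 1500`
(the mixed-group equilibrium of the relaxed cube lies at a cooperator
density of 0.827 in the well-mixed approximation for `alpha = -0.5`, and
finite systems fluctuate around it more widely). Desk-scale runs therefore
reproduce the *mechanism* of the half-cooperation plateau, while the exact
layer densities are only recovered at full scale.

In the strong-dilemma regime (`alpha = 0.15`, intermediate coupling and
overlap) cooperation stays very low (a few percent), as expected when
defection is the unique Nash equilibrium at both orders.

One regime deserves an explicit caveat. For moderately relaxed dilemmas
(`alpha` around -0.5) with high coupling and high overlap, these dynamics —
total payoffs across both orders, Fermi imitation at `w = 1/6`, and the
symmetric cross-order copying defined above — do **not** produce the
high-cooperation phase sometimes associated with such models: a well-mixed
balance shows the pairwise dilemma contributes a constant defector advantage
of `k_pair (T_pair - R_pair) = 0.4` that the triangle game's cooperative
pull (at most about 0.3 at `alpha = -0.5`) cannot overcome at any density,
and simulations at `N` up to 1500 and `1e5` MCS agree (stationary densities
below 0.1). Cooperation emerges under this update family only for strongly
relaxed dilemmas (`alpha` below about -0.6, e.g. density about 0.89 at
`alpha = -1.2`, `pswitch = 0.5`, `omega = 1`). Selection strength,
correlated slot updates, reservoir policy and absorbing-trigger variants
were all examined and do not change this conclusion; the package implements
the update equations as defined and reports what they produce.

## Numerical and design choices

* Payoffs are short decimals; invariant tests compare them at absolute
  tolerance 1e-12 or exactly.
* The Fermi function is evaluated as `1 / (1 + exp(-x))` in both the R and
  compiled paths (overflow-safe at both extremes, and bit-identical between
  paths, which the equivalence tests rely on).
* A player never serves as its own model (graph invariants exclude
  self-loops and degenerate triangles).
* `rewire_to_overlap()` draws candidate edges uniformly (not restricted to
  shared edges); convergence is still fast because the acceptance condition
  filters draws cheaply.
* Degenerate inputs: empty pairwise layers make the overlap undefined
  (error); isolated nodes are representable but refuse to pick a model;
  an absorbing initial state is rejected by the evolver.
* The CLI (`inst/cli/hypercoop`) is a thin wrapper over the exported
  functions: `build`, `simulate`, and `oracle` subcommands with CSV/JSON
  output; the package functions are the primary interface.

## Limitations

* Hyperedges are restricted to sizes 2 and 3; degrees are homogeneous; no
  weighted or directed interactions.
* The synthetic generator produces random-regular structures only — no
  hyperdegree heterogeneity, degree correlations, or community structure —
  so passing tests say nothing about dynamics on empirical contact
  structures.
* Only decrease-from-simplicial rewiring is implemented; arbitrary-overlap
  construction from scratch is out of scope.
* The bounded reservoir is an approximation of the dwell-time-proportional
  teleport law; its memory horizon is a numerical parameter, and very short
  horizons bias teleports toward the absorbing boundary while very long
  ones retain the transient. The default (100 snapshots, recorded every
  MCS) keeps the horizon two orders of magnitude below the scaled-down run
  length.
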