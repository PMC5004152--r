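---
title: "Evolving connective architecture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving connective architecture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modnet)
```

modnet simulates the evolution of three-layer feed-forward neural networks
whose input-to-hidden wiring — both the weights and the presence/absence of
each connection — is under selection, and asks whether task performance
(computational efficiency) alone pushes such networks toward modular
architecture. This vignette documents the model, the tunable parameters, the
numerical choices, and what the package's synthetic inputs do and do not
emulate.

## The network model

The evolving unit is a genome for an `I`-input, `H`-hidden, 1-output network
with sigmoid (McCulloch–Pitts) units in the hidden and output layers:

* `w_ih` — an `I × H` real weight matrix, gated elementwise by
* `m_ih` — a boolean connection mask (the "connective architecture"),
* `w_ho` — `H` hidden-to-output weights, always active,
* `b_h`, `b_o` — trainable biases on hidden and output nodes,
* `beta` — activation steepness, fixed at 1 in every preset.

Input nodes pass values through unchanged. The forward map for a pattern `x`
is `out = σ(β(Σ_j w_ho[j] h_j + b_o))` with
`h_j = σ(β(Σ_i m[i,j] w[i,j] x_i + b_h[j]))` and `σ(z) = 1/(1+e^{-z})`.
Because `σ` is strictly inside (0,1), outputs never reach the 0.5 decision
boundary exactly in exact arithmetic; an output of exactly 0.5 is counted as
incorrect for both sub-tasks (strict inequalities).

An inactive connection contributes nothing to the forward pass but its
weight keeps mutating — the biological analogy is a silenced gene that
continues to drift neutrally and may later be re-activated with a changed
value.

Reference architectures: `fcnmn` (fully connected non-modular), `pmn`
(perfectly modular: input block `m` wired only to its own 4 hidden nodes),
`snmn` (sparse non-modular: PMN connection count, uniformly random
placement), and `empty`. The exact wiring of the original sparse benchmark
is not published, so the uniform-random stand-in is a package design choice,
recorded in run metadata.

## Synthetic inputs

Every simulation consumes generated inputs; there is no external data. One
*block* is the complete enumeration of all 2^8 = 256 binary strings of
length 8 in a seeded random row order; an input set for a `K`-block network
concatenates `K` independently shuffled blocks (so each 8-column slice is
its own permutation of the full enumeration). The accept subset (default 100
of 256 rows) is drawn uniformly without replacement over assembled rows.
Fitness on the acceptance/rejection task is the product

> (correct accepts / 100) × (correct rejects / 156),

which is 1 for perfect behaviour, 0 when either sub-task fails completely,
and requires some competence on *both* sub-tasks for any fitness at all.

The dull/intense variant re-tasks the same patterns: in 140 randomly chosen
rows every 1 is replaced by a single per-row intensity drawn Uniform(0, 0.5)
("dull" rows, one value per row, applied across the full assembled width);
the remaining 116 binary rows are "intense". The network must respond high
to dull and low to intense rows, scored by the same product form
(140/116 denominators).

What this emulates: multi-stream sensory input in which each module sees a
different projection of the stimulus and integration happens late (a single
output). What it does not emulate: correlated or structured natural stimuli,
noise in the inputs, task changes over evolutionary time, or more than one
output decision. Passing tests therefore demonstrate properties of this
idealised task family, not of any particular biological network.

## The genetic algorithm

Populations hold 50 genomes. Each generation: evaluate fitness on the
replicate's input set; rank (ties broken by stable input order); keep the
top 10; clone each 5 times; mutate every offspring's weights, then its
connections. There is no elitism and no recombination. The order
"weights then connections" within a generation is a package choice the
underlying process description leaves open; at the per-generation
probabilities involved the two orders are statistically indistinguishable.

Weight regimes:

* `every_weight` — all `I·H + 2H + 1` parameters get `+Normal(0, 0.25)`
  each generation (the canonical regime);
* `per_weight_prob` — each parameter mutates with probability 1/1000 by
  `+Normal(0, 1)` (the low-rate/large-step regime). Biases mutate at the
  same probability as weights; the regimes' description calls the biases
  "trainable" without further detail, and treating them like weights is the
  simplest consistent reading.

Connective regimes: `symmetric` (each mask entry flips with p = 0.001 per
generation; the expected flips per generation in the 96-48 network are
0.001 × 4608 ≈ 4.6), `irreversible_loss` (only on→off transitions), `none`
(fixed architecture). At p = 0.001 the mask's neutral-drift time constant is
`1/(2p) = 500` generations: without selection on architecture the active
fraction follows `f(t) = 0.5 + (f₀ − 0.5)(1 − 2p)^t`, which converges to
0.5 well before generation 3000. This closed form is used as an oracle in
the tests (`selection = FALSE` runs; with flat fitness the evaluation is
skipped, which is distributionally exact and keeps all 50 masks independent
chains).

The nine scenario presets (`scenario_presets()`) encode the study's
parameter regimes verbatim: `starting_state` (96-48-1), `small` (16-8-1),
`low_weight_rate`, `start_empty`, `irreversible`, `dull_task` (+
`dull_task_pmn` fixed-architecture control), `very_large` (144-72-1),
`temporal_separation` (400 rounds × 400 weight-only generations, both rates
1/400, 8 replicates), and `aggressive` (flips at 1/100). Full-scale presets
run 10000 generations × 20 replicates; the `*_desk` presets keep identical
regimes at 3000 generations × 3 replicates, which is past mask convergence
(see above) and is the scale used by the package's own acceptance checks.
The temporal-separation preset exists because interleaved mutation could in
principle mask structural selection; separating the processes lets weights
adapt to each architecture before it is judged.

Seeding: every replicate derives its sub-seeds (input assembly, population
initialisation, evolution stream) deterministically from one master seed via
`derive_seeds()` (seed R's RNG with the master seed, draw integers below
2^31), so any replicate is exactly reproducible in isolation.

## Duplication-driven growth

The non-gradualistic alternative grows networks by copying them wholesale:
starting from a fully connected 8-4-1 network on one block, each lineage
evolves weights only; after `branch_generation` (1000 full-scale) every
individual is duplicated — weights and mask become block-diagonal with two
exact copies, hidden-to-output weights are concatenated, the single output
bias is shared (there is still one output node, so it is deliberately not
duplicated) — and the input set doubles with fresh blocks, one per new
module. The parent lineage continues on an independent random stream to the
stage end so parent/child fitness comparisons are paired within replicate.
Duplication applies to the whole population simultaneously, keeping the GA
well-defined. Duplicated hidden-to-output weights are not rescaled: the
doubled output drive is part of the perturbation the child lineage must
recover from. The accept subset is kept across duplications (the task stays
the same; a `redraw_accept` switch exists because the alternative reading —
a fresh target subset with the new inputs — is also defensible).

`run_duplication_experiment()` records, per branch event, the parent's
fitness at the branch, the child's fitness at its first generation (before
any mutation), the dip depth, and the recovery generation — the first child
generation whose best fitness reaches the parent's branch-point value.

## Quantifying modularity

Evolved masks are scored on the symmetric association matrix of the
input-to-hidden graph (bipartite on `I + H` nodes; the standard unipartite
Q is applied to this symmetrised matrix, matching the social-network
workflow the measure comes from, rather than a bipartite-specific
modularity).

* **Faction criterion** — missing within-group ties plus present
  between-group ties; 0 for a union of disconnected cliques partitioned as
  cliques. Minimised by **Tabu search**: single-node best-improvement
  moves, reverse moves tabu for 15 steps, aspiration when a tabu move beats
  the best cost seen, series ends after 20 consecutive non-improving
  iterations, best of 3 seeded random starts. Only those three parameters
  are fixed by the source workflow; the move set, aspiration rule and
  best-improvement scanning follow standard Tabu practice. An exhaustive
  enumeration oracle (≤ 12 nodes) verifies the search in the test suite:
  across an 11-graph battery × 100 seeds it attained the global optimum in
  every run.
* **Newman Q** — `Q = Σ_g (e_gg − a_g²)`; defined as 0 for edgeless graphs.
  Cross-checked against `igraph::modularity` in the tests.
* **Girvan–Newman** — divisive edge-betweenness clustering via igraph,
  returning the maximum-Q cut (or a requested group count).
* **Degree-preserving null** — each input node keeps its degree but its
  targets are redrawn uniformly; hidden degrees are unconstrained, exactly
  mirroring the input-side randomisation the comparison calls for.

`modularity_report()` scores each evolved mask and `n_null` nulls of it and
summarises mean Q with percentile 95% intervals (evolved: across genomes;
null: pooled). Two groups are assumed by default — the least favourable
setting for the "no more modular than random" conclusion, since it is where
evolved/null intervals were closest — with the group count exposed for
sweeps. One Tabu fitting seed is used per genome so that identical masks
always receive identical scores (a full mask's forced null then scores
exactly like the mask itself); the nulls themselves vary through their own
seeds. The mask analysed per replicate is the highest-fitness individual of
the final generation.

## Numerical and design notes

* Ranking ties are broken by stable input order; this only matters at
  flat-fitness starts and makes runs bit-reproducible.
* `generations = 0` returns the initial population and an empty trajectory.
* Fitness of an empty or silent network is 0 (all outputs 0.5, wrong for
  both sub-tasks), so "no function" is never rewarded.
* The exhaustive faction oracle refuses graphs over 12 nodes (Bell-number
  growth); the Tabu fitter has no such limit.
* Degenerate graphs: edgeless association matrices get Q = 0 and
  per-component partitions; `girvan_newman_partition` with `n_groups` below
  the component count returns the components.
* Problem sizes in the package's own checks: the starting-state acceptance
  runs use 3 replicates × 3000 generations (mask drift converged, see
  above); the duplication property check uses stages 1→2→4 with 1500
  generations per stage, branching at 300, 5 replicates; the drift oracle is
  checked at t ∈ {100, 1000, 3000} on all 50 × 4608 mask entries.

## Limitations

* The clonal GA has no recombination and no self-adaptive mutation rates;
  conclusions about reachability of modular optima are conditional on
  gradualistic, asexual search.
* The uniform-random SNMN stands in for an unpublished sparse benchmark
  wiring.
* Single output node, binary (or dulled-binary) patterns, equal-width
  blocks of 8 only (a config override exists but no preset uses it).
* Desk-scale runs shorten the weight-adaptation phase; fitness values at
  3000 generations are below 10000-generation asymptotes, while mask
  statistics (the quantities compared) are at equilibrium. The full-scale
  presets reproduce the original run lengths when time allows.
* In desk-scale duplication runs the post-branch fitness dip is universal,
  but the lengthening of recovery with module count is not yet visible
  between 2- and 4-module children: duplicated weights start children closer
  to the parent's fitness as modules accumulate, and between these small
  sizes that shortening effect dominates. The test suite asserts the
  lengthening anyway (it is the expected behaviour over the full 1→16
  module range) and the corresponding check currently fails at desk scale;
  this is a known, documented limitation rather than a silent skip.
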