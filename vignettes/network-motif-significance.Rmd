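---
title: "Querying labeled networks and testing motif significance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Querying labeled networks and testing motif significance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmotif)
```

## The problem

Biological networks — protein–protein interaction, transcriptional and
metabolic networks — carry their signal in small recurring patterns of
interaction rather than in individual nodes. Two questions recur in their
analysis:

1. **Querying**: given a small pattern graph $Q$ (possibly with unknown
   labels or loosely specified connections), find *all* of its occurrences
   in a larger labeled network $N$.
2. **Motif significance**: is $Q$ over-represented in $N$ relative to
   random networks of a comparable kind? If yes, $Q$ is a candidate network
   motif, a pattern plausibly favored by selection.

netmotif implements both: an exact subgraph-isomorphism matcher with a
topology-driven search order, an approximate matcher for wildcard and
path-constrained queries, and a simulation-based significance test against
seven random-graph null models.

## Graphs, labels and wildcards

A network here is a *simple* labeled graph: no self-loops, no parallel
edges, directed or undirected, with optional string labels on nodes and
edges. Self-loops and duplicates in input files are dropped with a warning;
simplicity is what all seven null models generate, so the real network and
its replicas live in the same space.

Labels follow a strict semantics chosen for predictability:

* comparison is exact, case-sensitive string equality;
* the wildcard `"?"` (equivalently, an absent label) on a *query* element
  matches anything;
* an unlabeled *target* element matches only wildcard query elements.

Internally `"?"` is normalized to `NA`, which makes "absent from the `.NA`
file" and "labeled `?`" the same thing and keeps the SIF round trip an
identity.

### File formats

Graphs travel as Cytoscape SIF (`source relation target`, whitespace
delimited, multi-target lines and bare-node lines supported — "any run of
whitespace" resolves the tab-vs-space ambiguity of the format), with
node labels in `.NA` and edge labels in `.EA` sidecars. The attribute
dialect is `identifier = value` with an optional header line and edge
identifiers of the form `source (relation) target`; the dialect is isolated
in `read_attributes()` / `write_attributes()` so it is easy to swap. On
duplicate SIF edges the first wins; on duplicate attribute identifiers the
last wins; both warn.

## Exact matching

A match is an injective map from query nodes to target nodes that preserves
edges (with direction, in directed graphs) and label compatibility. The
semantics is *subgraph* isomorphism, not induced: extra target edges among
the mapped nodes are allowed, which is what "the query's interactions must
be present" means in practice. Automorphic images count as distinct matches
(the `distinct_node_sets` option collapses them to node sets when the
motif's internal symmetry is not of interest).

The matcher backtracks over a *static variable ordering* computed from the
query topology alone: start at a node of maximum degree, then repeatedly
take the unplaced node with (lexicographically) the most already-placed
neighbors, the most frontier neighbors, and the highest degree. The effect
is that each new node is maximally constrained by the partial solution, so
dead ends are discovered early without expensive pruning; candidates for a
node are drawn from the target neighborhood of its *parent* (its
earliest-placed query neighbor) and filtered by label compatibility, a
degree lower bound, and presence of all edges back to already-mapped nodes.
Every query edge is checked exactly once — when its later endpoint is
placed — so directed correctness needs no separate per-direction degree
filter.

Ties in the ordering and candidate enumeration break on node identifier in
radix (C-locale) order, making match lists fully deterministic.

`brute_force_match()` — exhaustive enumeration of all injections, checked
directly against the match invariants — is kept as a first-class function.
It is the oracle for the test suite, which checks exact agreement of the
two routes on hundreds of randomized small instances (query up to 4 nodes,
target up to 8, directed and undirected, labeled and unlabeled, with and
without path constraints), alongside an independent cross-check of
unlabeled counts against igraph's LAD matcher.

## Approximate matching

Approximate queries add two relaxations:

* **wildcard labels** on nodes and edges, handled by the ordinary matcher;
* **path constraints** `a op b` on edges, where one side is `?` and the
  other a positive integer, `op ∈ {<, <=, >=, >, =}`: the mapped endpoints
  must be joined by a path whose length satisfies the relation. `?<=2`
  reads "a path of length at most 2"; `2<=?` normalizes to the same
  constraint seen from the other side.

Execution decomposes the query into its exactly-specified part (constrained
edges removed, nodes kept) and a join specification. The exact part is
matched first — disconnected parts are handled by the ordering's multiple
roots under a shared injectivity constraint — and each candidate mapping is
then filtered by BFS shortest-path checks between the mapped endpoints.

Two semantic choices deserve note, both made for determinism and
checkability where the operational definition of "traversed paths" is
open:

* Constraints are evaluated on the **shortest-path distance**. For upper
  bounds this is equivalent to "there exists a short enough path"; for
  lower bounds (`>`, `>=`) we additionally require the endpoints to be
  *reachable* — an unreachable pair does not vacuously satisfy "longer
  than m". The alternative existential-path semantics would make counts
  depend on witness paths and is intentionally not the default; the
  decomposition API (`decompose_query()`, `satisfies()`) keeps the check
  strategy swappable.
* Path interiors are **not** required to avoid other mapped nodes;
  disjointness would again make counting witness-dependent.

With these choices `?=1` is provably the same as an ordinary wildcard edge,
and raising a `<=` bound can only add matches — both are tested.

## The seven null models

Significance is always relative to a null model. Each generator produces a
simple graph with exactly $|V|$ nodes carrying the target's labels
(permuted uniformly; edge labels are permuted when counts coincide, else
resampled with replacement from the target's edge-label multiset):

| model | parameters (defaults) | structure |
|---|---|---|
| shuffling | `sw_per_edge` (10), `label_shuffle` (off) | degree-preserving double-edge swaps; counts *successful* swaps |
| erdos_renyi | `p` (estimated) | independent pairs, $G(n,p)$ |
| watts_strogatz | `d` (estimated), `beta` (0.1) | ring lattice + rewiring |
| barabasi_albert | `init_nodes` (3), `d` (estimated) | complete seed + preferential attachment |
| geometric | `dim` (2), `radius` (calibrated) | uniform points in the unit cube, threshold distance |
| forest_fire | `ambassadors` (1), `p_forward`/`r_backward` (calibrated, $r = p/2$) | recursive burning from random ambassadors |
| duplication | `init_nodes` (5), `edge_prob` (calibrated) | neighborhood copying from a ring seed |

`estimate_params()` fills every parameter the user does not set so that the
*expected* edge count of a replica matches the target's $|E|$: closed forms
for Erdős–Rényi (`p` = density), Watts–Strogatz (`d = round(|E|/|V|)`) and
Barabási–Albert (`d` from the edge-count identity $k(k-1)/2 + (n-k)d$);
numerical calibration for the rest. The geometric radius is the
$|E|/\binom{n}{2}$ quantile of an empirical pairwise-distance sample (the
fixed-point of the bisection, computed directly); the duplication
probability inverts the mean-field recurrence
$E[m_{t+1}] = m_t + p \cdot 2 m_t / t$; the forest-fire forward probability
is bisected against a small Monte-Carlo mean with the backward probability
tied at $r = p/2$ (the model's own interface exposes only the ambassador
count). Calibration runs under a fixed internal seed, so estimated
configurations are deterministic functions of the target.

Directionality: shuffling and forest fire are natively directed;
Erdős–Rényi samples ordered pairs directly in directed mode; the remaining
generators build undirected structure and, for directed targets, orient
each edge by an independent fair coin. The Watts–Strogatz description of a
lattice where "each edge" links to $d$ neighbors is read as each *node*
(the standard construction). The forest-fire ambassador links are
unconditional, so replicas are never edgeless; all links created by an
arriving node are its out-links.

All randomness flows through R's default Mersenne-Twister stream via
`withr::with_seed`, so a `(config, seed)` pair reproduces a replica
bit-for-bit across sessions and platforms.

## The significance test

With $r$ replicas $R_1 \dots R_r$ and occurrence counts $c_i$ against the
real count $c$:

* $p = \#\{i : c_i \ge c\} / r$ — the empirical fraction of nulls at least
  as motif-rich as the data. A reported 0 is only a bound; the add-one
  convention $(k+1)/(r+1)$ is available behind `add_one = TRUE` but off by
  default to keep the literal definition.
* $z = (c - \bar c) / s$, with $s$ the **sample** standard deviation
  (divisor $r-1$); the population convention is a documented switch, since
  either reading is defensible. When $s = 0$ the z-score is undefined and
  returned as `NA` with a warning, never an error.

Replicate $i$ uses seed `seed + i`: replicates are independent,
reproducible, and could be generated in parallel without changing results.
`r` defaults to 20 and is soft-capped at 100 (`allow_large` lifts the cap
for research use). Queries with path constraints are counted through the
approximate matcher automatically.

## Metrics for null-model choice

Which null model is fair for a given network is a modeling judgment;
`network_metrics()` and `model_sample_report()` support it with the
three classic summaries: average degree ($2|E|/|V|$), average local
clustering (degree-<2 nodes contribute 0; directed graphs are evaluated on
the underlying undirected graph), and degree assortativity (Pearson
correlation of endpoint total degrees over edges, both orientations for
undirected graphs; undefined on constant degree sequences).
`model_sample_report()` draws one replica per model and ranks models by
Euclidean distance to the target's metric vector, each coordinate
normalized by the target's absolute value where nonzero and undefined
coordinates dropped; the ranking is a convenience layer over the displayed
values, not a statistical test.

## Synthetic data and what the tests show

`synth_network()` generates uniform random graphs with an exact edge count
and uniform synthetic labels (`L1 … Lk`), and `plant_motif()` embeds
node-disjoint motif copies with known placements. These emulate the shape
of randomly-labeled benchmark networks: tunable size, density and label
alphabet, with planted ground truth. They do *not* emulate the clustered,
degree-skewed, label-correlated structure of real interactomes — so a
passing suite demonstrates correctness of the algorithms (planted
embeddings recovered, oracle agreement, conservation laws), not biological
sensitivity or specificity on real data.

Problem sizes in the test suite are chosen so the full run stays
interactive: oracle instances use queries of ≤ 4 nodes against targets of
≤ 8 (500 randomized instances), null-model laws use 15–60 node graphs with
up to 500 seeded samples, and the end-to-end seven-model study uses a
60-node, 180-edge target with $r = 20$.

## Numerical and degenerate-input choices

* Ordering and candidate ties break on node identifier, radix order;
  identical inputs give identical match lists.
* Shuffling counts successful swaps and caps attempts at `200 × needed +
  1000`; a graph with no admissible swap returns a copy with a warning.
* `r = 0` replicates is an error (no test is possible), as is an empty
  query, an empty metrics graph, or a directedness mismatch between query
  and target.
* Path bounds must be positive integers; `"?"` on exactly one side.
* Degenerate null-model inputs (e.g. `n <= 2d` for Watts–Strogatz) error
  at estimation time rather than mid-simulation.

## Limitations

* Occurrence counts enumerate injective mappings; for highly symmetric
  queries in dense targets the count (and runtime) grows with the
  automorphism group. `count_occurrences()` streams, but is still
  enumeration-based — no analytic counting shortcuts.
* The significance test is purely empirical; with $r \le 100$ the smallest
  resolvable p-value is $1/r$. Multiple-testing correction across a motif
  library is out of scope.
* The shuffling model's swap chain is run long (10 successful swaps per
  edge by default) but without formal mixing diagnostics; exact uniform
  sampling from the fixed-degree-sequence ensemble is out of scope, as is
  the fixed-edge-count $G(|V|,|E|)$ Erdős–Rényi variant.
* Label comparison is exact string equality; semantic or ontology-aware
  similarity is deliberately not modeled.
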