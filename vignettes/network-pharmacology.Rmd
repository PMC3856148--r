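---
title: "Scoring multi-component formulas on weighted interactomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring multi-component formulas on weighted interactomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem

Complex chronic diseases such as rheumatoid arthritis arise from an
unbalanced regulatory network rather than a single broken gene, and
multi-component herbal formulas are believed to act by collectively
modulating that network through many weak inhibitions. Comparing such a
formula with single-target drugs therefore needs a network-level currency.
`netpharm` provides one: both disease and drug are represented as seed
vectors on a weighted protein–protein interaction (PPI) network, both are
propagated to steady state by a random walk with restart, and the drug's
disease-specific effect is the inner product of the two propagation
vectors, calibrated against a permutation null.

## Network construction

The interactome is read from a STRING-style edge list (`read_edge_list()`,
with `weight_scale` to divide raw 0–1000 confidence scores; sources that
pre-normalize to [0, 1] use the default of 1). `build_network()` keeps all
edges with weight at or above `high_conf` (default 0.9) and then *rescues*
focus genes — disease genes and drug targets — that fall below the cut: for
each such gene present in the raw edge list, its incident edges with the
maximal sub-threshold weight are added, all ties included. Reading the
rescue rule ties-included (rather than one arbitrary edge) keeps the
construction order-invariant and deterministic.

Three normalisations are applied silently because every downstream stage
assumes a simple graph: self-loops are dropped (the walk and the topology
measures are defined without them), duplicate edges keep their maximum
weight (a confidence score is an upper bound of evidence), and isolated
nodes are removed so the transition operator has no zero column. Symbols
are compared case-insensitively and stored uppercase, since gene symbols
arrive in mixed case across source databases.

## The propagation model

The walk iterates

$$x_{t+1} = (1-r)\,W x_t + r\,x_0$$

where $W$ is the *column-normalized* weight matrix:
$W_{uv} = w(u,v) / \sum_{u'} w(u',v)$. Move probabilities must be
proportional to interaction reliability, which forces this normalization —
iterating with a raw adjacency matrix diverges, so the raw form is not an
option even where descriptions are loose about it. Column stochasticity
plus the restart term conserve total seed mass, a property the tests check
to 10^-8.

Parameters, defaults, and why:

* `r = 0.3` — restart probability; the standard robust choice in
  network-based gene prioritization. Larger `r` keeps mass near the seeds,
  smaller `r` approaches the weighted-degree stationary distribution.
* seed strengths — 1 for disease genes and approved-drug targets, 0.01 for
  herbal-component targets. The two-orders-of-magnitude gap encodes the
  typical inhibition-potency ratio between designed drug molecules and
  natural compounds (e.g. IC50 comparisons of natural compounds against
  their designed counterparts). Because the walk is linear in $x_0$, the
  strength is a pure scale factor: component scores at 0.01 are exactly
  0.01 times the unit-strength run, and z-scores are invariant to it.
* `tol = 1e-10` (L1 on successive iterates) and `max_iter = 10000` — far
  below any reported score precision; with `r = 0.3` the iteration contracts
  at rate at most 0.7, so convergence takes roughly 60–70 iterations.
  Non-convergence is an error carrying the last residual, never a silent
  return.

Disease genes or targets absent from the network are dropped with a warning
and recorded on the result (`dropped_seeds`); a seed set entirely off the
network is an error. The effective (on-network) seed count is what the
permutation null matches.

## Effect score, whole-formula convention, and the permutation null

$E = \langle x_{\text{disease}}, x_{\text{drug}} \rangle$ is large when
drug influence concentrates where disease influence is. For a whole
formula, the default seed set is the **union** of the component target sets
at strength 0.01 — a target shared by two components is seeded once. An
additive convention (shared targets receive summed strength) is available
via `formula_seeds(mode = "additive")`; how shared targets should be
weighted is genuinely underdetermined, so both are exposed and neither is
claimed canonical. Under the union convention with disjoint component
targets, linearity makes the formula score exactly the sum of component
scores; with overlapping targets it is bounded above by that sum.

The null model (`drug_significance()`) draws `n_perm = 3000` random target
sets of the same size uniformly from all network nodes, recomputes `E` for
each, and reports $z = (E - \bar E_r)/\Delta E_r$ with the sample (n−1)
standard deviation and the conventional $|z| > 3$ significance flag.
Uniform sampling is the literal reading of "random target sets"; note that
hubs carry large propagation mass, so a degree-matched null would shift z —
users comparing drugs with very hub-biased target sets should bear this in
mind. The disease propagation is computed once and reused across all drugs
and permutations; each drug's permutation seed is derived from the master
seed keyed by the drug id, so adding a drug never perturbs another drug's
null.

## Pathway enrichment

For a target set against a GMT collection, the universe $N$ is the union of
all pathway members (not the whole interactome — enrichment asks about the
pathway vocabulary actually under study), $K$ the targets inside it, and a
pathway of $n$ genes containing $k$ targets gets the upper-tail
hypergeometric probability $P(X \ge k)$. Numerics: the pmf is evaluated in
log space via `lchoose` and the tail is the direct log-sum-exp over
$i = k..\min(n, K)$ rather than one minus the lower tail, which would lose
all precision exactly where it matters (small P). $k = 0$ gives $P = 1$;
values outside the support are zero.

Significance uses the raw `p < alpha` with `alpha = 0.01`, matching the
convention of reporting uncorrected exact-test P values at a strict cut;
Benjamini–Hochberg q-values are emitted alongside for users who prefer a
controlled false-discovery rate. Being a discrete exact test, the realised
type-I rate is *below* the nominal level (there is rarely a k with tail
probability exactly 0.01); the acceptance checks therefore compare the
simulated rate against the exact discrete rejection rate, not against the
nominal level from above.

## Disease subnetwork and topology

`extract_top_fraction()` keeps the `floor(fraction * n)` nodes with the
highest disease propagation score (default 3%) and induces their subgraph.
Ties are broken by score descending then symbol ascending, so the selection
is deterministic; an optional `drop_zero_scores` excludes unreached nodes
before taking the fraction (relevant on disconnected inputs). The count and
percentage of disease genes retained is reported.

Topology is computed on the unweighted simple view — degree, k-core
decomposition (coreness = the largest k a node survives in the recursive
deletion of degree < k nodes, computed per connected component), and exact
betweenness over unordered pairs normalized by $(n-1)(n-2)/2$; pairs in
different components contribute zero. Weights serve only the propagation:
the integer degrees and [0, 1] betweenness values of the topology report
are meaningful only unweighted. `topology_report()` joins these with
disease-gene membership and the components targeting each node, and
summarises the fraction of targeted nodes above mean degree, above mean
betweenness, and in the maximal core (reported as `NA` when no target is on
the subnetwork).

## The synthetic-data generator

`generate_bundle()` produces every input the pipeline needs, with the
statistical structure the analysis assumes:

* **Network** — preferential attachment (clique seed of `edges_per_node`
  nodes; each new node attaches to `edges_per_node` distinct existing nodes
  with probability proportional to degree), giving connected graphs with
  heavy-tailed degrees, which the hub/k-core analysis presumes.
  Erdős–Rényi graphs would make the topology stage vacuous. Edge weights
  are i.i.d. uniform on `[weight_low, weight_high]`; the analysis needs
  only weights in (0, 1], not a calibrated confidence distribution.
* **Disease module** — breadth-first expansion from a random top-decile-
  degree anchor: a connected neighbourhood of the interactome, the way
  disease genes cluster.
* **Drugs** — one *effective* drug whose targets are disease-module
  proteins sampled with probability proportional to degree (drug targets
  are characteristically hub proteins — the TNF/interleukin pattern — and
  this is precisely the structure the downstream centrality summaries
  measure), one *random* drug with uniformly sampled targets, and a
  three-component formula drawing targets from the effective drug's first
  neighbourhood so components overlap the disease vicinity.
* **Pathways** — sets of sizes uniform in `pathway_size_range`, one planted
  enriched set containing a chosen fraction of drug targets (its size can
  be fixed via `enriched_size` when the target pool is small), the rest
  uniform background.

Defaults (200 nodes, `edges_per_node` 3, weights U[0.5, 1], module of a
tenth of the network, 50 pathways of 10–40 genes) are the desk scale at
which every stage has measurable signal while the full test suite runs in
minutes; the test files state where they use other sizes (e.g. 1000-node
universes for enrichment calibration, 500-node bundles for pipeline
timing, 40–100 nodes for brute-force topology oracles). Everything is a
pure function of its config and seed — seeds are explicit arguments, never
global state.

What the generator does **not** emulate: STRING's empirical degree and
score distributions, correlated edge confidences, module overlap with
pathway membership, or target promiscuity distributions. Passing tests
show the machinery is correct and well-calibrated on networks with planted
structure; they do not certify effect sizes on real interactomes, where
z-scores at interactome scale (thousands of nodes, dozens of targets) are
typically far larger than at desk scale.

## Degenerate inputs and edge cases

Empty networks after thresholding, seed sets entirely off the network,
pathway collections that contain none of the targets, zero-variance nulls,
and empty top-fraction selections are all errors with specific messages —
never silently empty results. Focus genes absent from the raw edge list are
reported in the network's `unmapped` attribute. A subnetwork may legally
contain isolated members (induced subgraphs lose edges); the parent
network class forbids them.

## Known limitations

* The permutation null is uniform over nodes; no degree-matched or
  target-universe-restricted null ships by default.
* The propagation kernel is RWR only — no heat diffusion or other kernels.
* No identifier mapping: symbols are matched as uppercase strings.
* Betweenness and k-core are unweighted by design; weighted variants would
  need a different definition of shortest path.
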