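---
title: "Similarity-popularity link prediction: model, evaluation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-popularity link prediction: model, evaluation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linksp)
```

## The model

Link prediction asks, for every non-adjacent node pair of an observed
network, how likely it is that the pair is in fact connected — because the
edge was missed during data collection (a typical situation in
protein-protein interaction screens) or because it will appear as the
network grows. `linksp` implements a global, parameter-free predictor built
on the similarity-popularity view of complex networks: the chance that two
nodes connect trades off how *popular* each node is (degree-like), how
*similar* the two nodes are (distance-like in a hidden space), and how much
*attraction* their shared neighbourhood exerts.

Each candidate pair $(i,j)$ receives the score

$$\psi_{ij} = (\pi_{ij} + \eta_{ij})\, s_{ij},$$

with all three ingredients computed from the observed topology alone:

* **Popularity** $\pi_{ij} = \dfrac{\phi(\kappa_i)+\phi(\kappa_j)}
  {2\,\phi(\kappa_{\max})}$, where $\phi(x)=\log(x+1)$ and $\kappa$ are
  degrees. The shift inside the logarithm keeps isolated nodes (degree 0,
  routinely produced by test-edge removal) well defined; the denominator
  normalises to $[0,1]$.
* **Local attraction** $\eta_{ij} = 1-\prod_{k\in\Gamma_{ij}}
  \phi(\kappa_k)/\phi(\kappa_{\max})$ over the common neighbours
  $\Gamma_{ij}$, set to $0$ when $\Gamma_{ij}$ is empty. Low-degree common
  neighbours are strong evidence for a link (they connect to few nodes, so
  connecting to both $i$ and $j$ is informative); high-degree ones are
  weak evidence.
* **Similarity** $s_{ij} = 1/(1+d_{ij})$, where $d_{ij}$ is a shortest-path
  distance on a re-weighted copy of the network: every edge gets the length
  $\omega(i,j) = 2\pi_{ij}/(1+\eta_{ij})$. This *factors out* popularity
  and attraction: hubs connect over large hidden distances, so their edges
  are long; strongly attracted neighbourhoods sit close together, so their
  edges are short. What remains in the shortest-path metric is an estimate
  of hidden dissimilarity. Pairs at infinite distance get $s=0$ and hence
  $\psi=0$.

Since $\pi,\eta,s \in [0,1]$, scores lie in $[0,2]$.

### The horizon cut-off

Exact all-pairs distances cost $O(nm + n^2\log m)$ with repeated Dijkstra
runs. `linksp` instead bounds the number of edges a path may use by a
*horizon* $h$: paths longer than $h$ edges are discarded and pairs beyond
the horizon are treated as infinitely distant. The default is $h=2$; top
precision is empirically insensitive to $h$ (the package's horizon study
reproduces this at desk scale), while the cost drops dramatically because
only each node's 2-hop neighbourhood is explored.

Finite-horizon distances are computed by $h$ synchronous rounds of edge
relaxation over hop-indexed states. This is deliberate: the lightest path
need not have the fewest hops, so a standard early-terminated relaxation
(or a Dijkstra run truncated at depth $h$) can return wrong answers. All
edge lengths are strictly positive on graphs with minimum degree 1, so
minimising over *walks* of at most $h$ edges — which the relaxation does —
equals minimising over paths. At $h=\infty$ a priority-queue Dijkstra
(igraph) is used. The test suite checks the finite-horizon routine against
exhaustive enumeration of all walks on 200 random graphs with up to 12
nodes.

## Baselines

Seven classical local indices (`ADA`, `CNE`, `CH`, `HPI`, `JID`, `PAT`,
`RAL`; see `?baseline_scores`) are implemented behind the same interface
and tie-break contract as the main predictor, so paired comparisons are
exact like-for-like. Conventions worth noting: natural logarithms
throughout (any fixed base cancels in $\pi$ and $\eta$, but not in the
Adamic-Adar index, where natural log is the literature standard); `HPI`
and `JID` return 0 for pairs with an isolated endpoint (such pairs have no
common neighbours, and 0 is the limit of the ratio); `CH` uses the
$\Gamma_{ij}$-restricted internal-degree sum
$\sum_{k\in\Gamma_{ij}} |\Gamma_k \cap \Gamma_{ij}|/\kappa_k$, not later
variants of the index.

## Evaluation design

Performance is measured by repeated random edge removal: each trial hides
`round(fraction * m)` edges (default 10%, minimum 1) and presents the rest
to the predictors; all nodes are kept and connectivity is *not* enforced,
so removal can isolate nodes — the predictor must cope, which is why
$\phi(0)=0$ matters. Degrees, $\kappa_{\max}$ and common neighbourhoods
are always computed on the training graph, never on held-out edges.

Metrics: **top-precision** (fraction of test positives in the top-$k$
ranked candidates, $k$ = number of removed edges — the primary metric),
**AUROC** (tie-aware Mann-Whitney formulation; ties credit 1/2), and
**AUPR**, computed as average precision — the step-wise integral of the
precision-recall curve — rather than trapezoidal interpolation, which is
the standard choice for ranked retrieval and is stable when the positive
set is small. **Relative top-precision** divides top-precision by the
analytic random-ranker expectation $k/N$, which makes results comparable
when test-set sizes differ (e.g. across snapshot pairs of a growing
network; `temporal_pairs()` enumerates the earlier/later couples of such a
design).

Ties in a ranking are broken by a seeded random shuffle stored in the
score table's row order. The alternative — leaving ties in input order —
would hand methods that emit many tied scores (e.g. `CNE`) a systematic,
order-dependent bias in top-$k$ metrics.

Aggregation across networks deliberately avoids averaging raw metrics
(networks differ too much in difficulty). Instead, per network, every
algorithm pair is compared by a two-tailed paired t-test on the per-run
metric; significant wins score $+1$, losses $-1$, non-significant pairs
$0$; summed scores are converted to within-network ranks (average-rank
ties), and ranks are averaged across networks (*average significant
rank*, lower is better). Zero-variance differences are declared
non-significant when the means are equal (the t statistic is undefined
there, and "no detectable difference" is the honest reading) and
significant when a constant nonzero margin separates the methods. Across
networks, algorithm pairs are compared by one-tailed two-sample
Mann-Whitney-Wilcoxon tests on the per-network ranks (normal
approximation: rank data are tie-heavy, which rules out the exact null
distribution), jointly adjusted by the Benjamini-Hochberg-Yekutieli
procedure, which remains valid under the dependence among overlapping
pairs.

All randomness flows from one master seed through the documented scheme in
`run_seed()` (an affine map into the 32-bit range per network and run), so
any single cell of a benchmark can be reproduced in isolation and reruns
are byte-for-byte identical, tie orders included.

## Synthetic networks

Three seeded generators cover the standard benchmark families. They are
first-class, tested code, not fixtures:

* **Barabasi-Albert** (`generate_ba`): growth with preferential
  attachment from a $(k{+}1)$-clique seed. The clique convention makes the
  edge count the closed form $m = k(n-k-1) + \binom{k+1}{2}$, which the
  tests pin exactly; the degree-distribution tail attains exponent
  $\approx 3$.
* **Watts-Strogatz** (`generate_ws`): ring lattice ($k$ previous, $k$
  next) with per-edge rewiring of the far endpoint at probability $p$,
  skipping moves that would create loops or duplicates — so $m = nk$
  always.
* **nPSO** (`generate_npso`): popularity-similarity growth in the
  hyperbolic disk with angular coordinates from a $C$-component Gaussian
  mixture (equally spaced means), yielding $C$ communities. Internals the
  benchmark literature leaves as model constants are exposed as arguments
  in one place: radial schedule $r_t = 2\log t$, popularity fading
  $\beta = 1/(\gamma-1)$, Fermi connection probabilities with the standard
  cut-off radius $R_t$, mixture spread $\sigma = (2\pi/C)/6$, and
  exactly-$k$ weighted target sampling (which pins the mean degree at
  $\approx 2k$). Temperature $T$ flattens the connection probabilities,
  mixing communities and lowering clustering — the tests verify the
  monotone effect.

`benchmark_grid()` returns the full parameter grids of the synthetic
benchmark (54 nPSO and Watts-Strogatz combinations, 18 Barabasi-Albert).

### What the generators do and do not emulate

The generators reproduce the *topological* regimes that separate the
predictors: scale-free degree mixing (BA), locally clustered but
degree-homogeneous small worlds (WS), and community-structured hyperbolic
geometry (nPSO). They do not emulate measurement noise, spurious edges,
node attributes, or the temporal correlation of real interaction screens.
Tests passing on them therefore establish that each method behaves as the
theory predicts in its favourable and unfavourable regimes — popularity
methods winning on BA, neighbourhood methods on dense clustered graphs,
the similarity-popularity predictor on sparse weakly clustered graphs —
not that any fixed accuracy carries over to a particular real network.

## Problem sizes and numerical choices

The packaged experiments run at desk scale, chosen so the full suite
completes comfortably on one core while leaving the stochastic checks
enough resolution: qualitative method-ordering reproductions use nPSO and
BA networks of 600-1000 nodes with 20-30 removal trials and are asserted
at three standard errors of the paired per-run differences; the
random-ranker calibration uses a 300-node BA network and 500 trials
(1000 in `scripts/acceptance.R`). Degenerate inputs are rejected loudly
rather than patched: an edgeless graph has no $\kappa_{\max}$ and no
weight map; candidates that are existing edges violate the scoring
contract; `AUROC`/`AUPR` require at least one positive and one negative.
Distances use double precision throughout; the only tolerance in the
package's own logic is none — equalities in tests are asserted at
`1e-9`-`1e-12` where algebra guarantees them.

## Known limitations

* Candidate enumeration materialises all $n(n-1)/2 - m$ non-edges;
  practical up to a few thousand nodes. For larger networks, supply an
  explicit candidate list (the CLI's `--candidates`) — e.g. all pairs
  within two hops.
* The finite-horizon relaxation is a dense-per-source loop in R; it is
  fast at desk scale but does not exploit the sparsity tricks a compiled
  implementation would.
* `generate_npso` follows the standard growth equations but makes no
  attempt to replicate any specific reference implementation's random
  stream; only distributional properties are comparable.
* The statistical-ranking machinery presumes paired runs (identical
  splits across methods); feeding it unpaired results silently answers a
  different question. `run_benchmark()` constructs the pairing itself and
  is the recommended entry point.
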