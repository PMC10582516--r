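---
title: "Models and methods behind bionetkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bionetkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

bionetkit analyses undirected biological networks — the package was shaped
around protein–protein interaction (PPI) graphs, where vertices are
proteins identified by stable string IDs (Entrez gene IDs in practice) and
edges are physical interactions. This vignette explains the models the
package implements, the tunable parameters and their defaults, the
numerical choices, and what the synthetic test surface does and does not
establish about real data.

## Networks, identifiers, and annotation

Vertex identifiers are always handled as stripped strings, never integers:
gene identifiers are labels, and coercing them through numeric types is a
classic source of silent corruption. Graphs are simplified on construction
(self-interactions and duplicate records are measurement artefacts in
interaction data). When the largest connected component (LCC) is
requested and several components tie for size, the component containing
the lexicographically smallest vertex ID wins, so the operation is
deterministic. Annotation terms attached to a vertex are deduplicated,
sorted, and joined with semicolons — the attribute string is canonical, so
two annotation runs can be compared with a plain diff.

The edge-list dialect is deliberately conservative: the first two
whitespace- or comma-separated tokens of a line are the endpoints, `#`
lines are comments, and a first line is dropped as a header only when both
its tokens are non-numeric *and* appear nowhere else as vertex IDs. The
last condition keeps header detection from eating a legitimate edge.

## Vertex topology

`calc_centrality()` produces seven measures. Betweenness is reported as
raw shortest-path pair counts (the common graph-library default), the
clustering coefficient of degree-<2 vertices is defined as 0 so the matrix
is total, PageRank uses damping 0.85, and shortest-path statistics are
computed over reachable vertices only, so disconnected inputs are allowed.

Semi-local centrality aggregates two-hop neighbourhood sizes: with
$N(w)$ the number of distinct vertices within distance two of $w$
(excluding $w$), $Q(u) = \sum_{w \in \Gamma(u)} N(w)$ and
$CL(v) = \sum_{u \in \Gamma(v)} Q(u)$. It sits between degree (too local)
and betweenness (too global, and expensive) as a ranking of local
influence. Values are normalised by the maximum observed $CL$, which puts
them in $[0,1]$ with the top vertex at exactly 1; a theoretical bound
could be used instead, but no closed bound is tight across topologies, so
the empirical maximum is the documented choice.

## Scale-free structure

### Discrete power-law fit

Degree distributions are fitted with the discrete power law
$p(k) = k^{-\alpha} / \zeta(\alpha, x_{\min})$, $\zeta$ being the Hurwitz
zeta function (evaluated by a 400-term direct sum plus an Euler–Maclaurin
tail, accurate to below $10^{-10}$ in the relevant range). For each
candidate $x_{\min}$ among the observed degrees, $\alpha$ is the maximum
of the exact discrete likelihood (one-dimensional optimisation on
$(1.01, 25)$), and the reported $x_{\min}$ minimises the
Kolmogorov–Smirnov distance between the empirical and fitted tail CDFs.
Both CDFs are right-continuous step functions on the same integer support,
so the KS supremum is attained at observed support points; the left-limit
comparison used for continuous data would wrongly count the jump heights.
The $x_{\min}$ search requires at least 10 tail points (configurable), so
fits are never vacuous. An optional semi-parametric bootstrap (body
resampled empirically, tail from the fitted law; off by default because of
its cost) yields the usual plausibility p-value.

The companion sampler draws from the same family by inverse CDF (table to
$10^5$, exact zeta-ratio bisection beyond), so parameter-recovery tests
have an oracle that shares only the distribution, not the fitting code.

### Entropy rate and perturbation

For positive vertex weights $x$ the package uses the random walk with
$p_{ij} = x_j / \sum_{k \in \Gamma(i)} x_k$, whose stationary distribution
is available in closed form, $\pi_i \propto x_i \sum_{k \in \Gamma(i)}
x_k$ (validated against the eigenvector of the transition matrix in the
tests — no power iteration is needed). The entropy rate
$SR = \sum_i \pi_i S_i$, $S_i = -\sum_j p_{ij} \ln p_{ij}$, is reported in
nats; for a $k$-regular graph with uniform weights $SR = \ln k$, and
$SR \le \ln(\max_i k_i)$ always. The computation requires a connected
graph (the stationary distribution is otherwise not unique); the error
message points at LCC extraction.

The perturbation protocol needs no expression data: all vertices get a
uniform baseline weight, each vertex in turn is set to the perturbed
weight, and the global $SR$ is recorded — over-expression is modelled as
baseline 2 with perturbation 14, under-expression as baseline 16 with
perturbation 14. On scale-free-like graphs the magnitude of the response
grows with degree, and plotting both directions against log degree
(`autoplot()`) shows the characteristic two-branch pattern. One caution
from our own numerical work: with these weight ratios the *rank
correlation* of the perturbed rate with log degree is negative for both
directions on Barabási–Albert graphs; a positive under-expression branch
only appears for perturbation ratios slightly above 1. The tests therefore
assert the identity perturbation, the closed forms, and the over-expression
direction, not a sign claim for the under-expression branch.

## Community structure

Six standard algorithms are delegated to igraph (fast-greedy, walktrap,
leading-eigenvector, louvain, infomap, spin-glass with a `spins`
parameter). The package's own contribution is the fine-tuned spectral
method: recursive bisection by the leading eigenvector of the modularity
matrix $B_{ij} = A_{ij} - k_i k_j / 2m$, using the generalised matrix
$B^{(g)}_{ij} = B_{ij} - \delta_{ij} \sum_{k \in g} B_{ik}$ for
subdivisions. After each proposed split a Kernighan–Lin stage sweeps the
vertices — each moved at most once per sweep, the best visited prefix
kept, sweeps repeated until none improves — and recursion stops when the
leading eigenvalue or the modularity gain drops below $10^{-9}$.

Fine-tuning a split can, rarely, steer the recursion to a worse stopping
point than the plain split would reach (the refined bisection is better
locally but divides less favourably downstream). The implementation
therefore runs the recursion with and without per-split refinement,
polishes both results with a global loop of partition-level KL sweeps and
community merges (both applied only when they increase $Q$), and keeps the
better partition. In our checks over hundreds of random graphs this never
scored below igraph's leading-eigenvector result, and on planted-partition
graphs (4 blocks × 16 vertices, $p_{in} = 0.5$, $p_{out} = 0.02$) it
recovers the planted blocks exactly.

Modularity itself is computed from the per-community form
$Q = \sum_c (e_c/m - (d_c/2m)^2)$; ties anywhere are broken by lowest
vertex or community index. The normalised modularity divides the observed
$Q$ by the mean $Q$ that the *same* algorithm achieves on
degree-preserving rewired copies (default 10, each rewired with $10|E|$
swap attempts); the choice of null model and replicate count is open in
the literature, so both are parameters and the null mean and SD are
reported alongside the ratio. `recluster()` re-runs a clusterer inside
every community above a size threshold — once by default, to convergence
with `recurse = TRUE`. The community-aware layout places independently
force-directed communities on a grid, cells sorted by size and scaled with
$\sqrt{|c|}$, which keeps bounding boxes disjoint and makes the layout
practical for very large graphs.

## Consensus, robustness, bridgeness

The consensus matrix records, over repeated clustering of random vertex
subsamples (default 80% of vertices, 500 replicates, per-replicate seeds
derived from the master seed by a counter), the frequency with which each
pair lands in one community. The denominator is the number of replicates
in which *both* vertices were sampled, not the total replicate count —
with the total, every entry would be biased low by a factor of roughly the
sampling fraction squared. Pairs never co-sampled (rare at the defaults)
are reported and scored 0.

Cluster robustness is the mean consensus over within-cluster pairs;
singletons score 1 by convention (there is no pair to disagree).
Bridgeness converts a vertex's consensus mass per community,
$p_{ic} \propto \sum_{j \in c,\, j \ne i} M_{ij}$ (renormalised to sum 1;
an all-zero row falls back to the uniform affiliation), into
$B_i = 1 - \sqrt{K/(K-1)}\,\sqrt{\sum_c (p_{ic} - 1/K)^2}$ — the scaled
distance of the affiliation vector from the uniform one, so $B_i = 0$ for
a vertex clearly in one community and $B_i = 1$ for a perfectly even
"global bridge". The influence view pairs $B$ with any normalised
centrality (semi-local centrality by default) at 0.5/0.5 thresholds; a
vertex above the bridgeness threshold but below the centrality threshold
is a global bridge, the converse a local hub.

## Annotation-pair statistics

For vertex sets $A, B$ the package uses nearest-member distances:
$d_{AA}$ averages each member's distance to its nearest other member,
$d_{AB}$ averages, over members of both sets, the distance to the nearest
member of the opposite set — members of both sets contribute distance 0.
The separation $s_{AB} = d_{AB} - (d_{AA} + d_{BB})/2$ is negative when
the sets interpenetrate (as comorbid disease modules do) and positive when
they occupy distinct neighbourhoods. Unreachable members are dropped with
a reported count rather than imputed.

Significance comes from annotation permutation, not edge rewiring: each
term keeps its vertex count but its members are re-drawn uniformly,
*independently across terms*. The independence matters — permuting whole
per-vertex annotation strings preserves co-annotation, and since shared
members are the main driver of negative $s_{AB}$, that null would leave
exactly the signal of interest in the null distribution. Empirical
p-values use the add-one correction $p = (1 + \#\{s_{null} \le
s_{obs}\})/(n_{perm}+1)$ and address the overlap direction; the separation
direction is obtained by reversing the inequality. Bonferroni is applied
over the tested pairs and q-values use the Benjamini–Hochberg estimator —
with the tens of pairs typical here, $\pi_0$-smoothing estimators are
unstable, so the simpler estimator is the default.

Over-representation analysis is the one-sided hypergeometric tail
$P(X \ge k)$ for the overlap of each (group, term) pair against the
user-supplied universe, BH-adjusted across all rows, with the overlapping
vertices listed. Intra-class edge enrichment counts edges whose endpoints
share a class label and compares against class-size-preserving label
permutations; the analytic null mean
$\sum_c \frac{n_c (n_c - 1)}{n(n-1)}\,|E|$ is used as a cross-check in the
tests.

## Synthetic study conditions

The generators define the conditions every stochastic claim is tested
under: planted partitions (4 blocks × 16 vertices at $p_{in} = 0.5$,
$p_{out} = 0.02$ for recovery; smaller or sparser variants where a test
needs them), discrete power-law samples ($\alpha = 2.5$, $x_{\min} = 1$,
$n = 10^4$ for recovery within $\pm 0.1$), annotated planted graphs with
same-block / cross-block / random term placement, and a toy bipartite
disease–gene network. All generators are bit-reproducible given a seed.

What passing these tests shows — and does not. The planted-partition model
has homogeneous blocks and independent edges; real PPI networks have
heavy-tailed degrees, overlapping complexes and ascertainment bias, so
perfect recovery here does not promise perfect communities there. The
separation statistic behaves differently at toy scale than on
thousand-vertex networks: on a small dense graph two disjoint halves of
one block score near 0, because nearest-member distances saturate at 1;
the negative-overlap regime is driven by shared members and by sparse
large-graph geometry. The permutation-calibration check pools four
independent annotation draws (420 pairs) because p-values of pairs sharing
one term draw and one null batch are dependent, and a Kolmogorov test on
dependent values false-alarms.

## Numerical choices and limitations

Natural logarithms throughout entropy computations; eigen-decompositions
are dense and symmetric (communities of a few thousand vertices are fine,
larger ones should be pre-split); tolerances are $10^{-9}$ on modularity
gains and eigenvalues and $10^{-12}$ on closed-form identities in tests;
problem sizes in the default test run are 64-to-500-vertex graphs, 100–500
consensus replicates and 100 permutations, chosen to exercise every code
path at comfortable cost. Spin counts for the spin-glass variants are
exposed as a parameter rather than fixed, and the consensus denominator
and permutation-null conventions are documented above precisely because
reasonable alternatives exist; both alternatives are a flag away for
sensitivity analysis. Weighted-edge semantics, directed graphs,
ranked-list enrichment (GSEA) and ontology-graph propagation are out of
scope.
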