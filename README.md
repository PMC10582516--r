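# bionetkit

Topological analysis of biological networks — typically protein–protein
interaction (PPI) networks from proteomics experiments, but equally
disease–gene or any other undirected molecular network. The package covers
the full pipeline a network study walks through: build and annotate the
graph, quantify vertex topology, test for scale-free structure, detect and
evaluate community structure, score per-vertex bridgeness from consensus
clustering, and test how annotation sets (diseases, functions) are placed
on the network.

All tabular results are tibbles; fitted objects carry broom-style `tidy()`
/ `glance()` methods and ggplot2 `autoplot()` methods, so results drop
straight into dplyr/ggplot2 workflows. The graph container is a plain
`igraph` object throughout.

## What it computes

**Vertex topology.** `calc_centrality()` returns degree, betweenness,
clustering coefficient, PageRank, mean/SD of shortest-path length, and a
semi-local centrality `CL(v) = Σ_{u∈Γ(v)} Σ_{w∈Γ(u)} N(w)` (with `N(w)`
the two-hop neighbourhood size), normalised to [0, 1]. `random_graph()`
and `compare_to_random()` provide G(n,p), Barabási–Albert and
edge-perturbation null models.

**Scale-free structure.** `fit_powerlaw()` fits the discrete power law
`p(k) = k^(−α) / ζ(α, x_min)` by maximum likelihood with the lower bound
`x_min` chosen to minimise the Kolmogorov–Smirnov distance of the tail
fit, plus an optional semi-parametric bootstrap. `entropy_rate()` gives
the entropy rate `SR = Σ_i π_i S_i` of the vertex-weighted random walk
(`p_ij = x_j / Σ_{k∈Γ(i)} x_k`, `π_i ∝ x_i Σ_{k∈Γ(i)} x_k`), and
`perturb_entropy()` perturbs each vertex in turn (over-expression 2→14,
under-expression 16→14) to probe scale-free organisation without
expression data.

**Community structure.** `cluster_network()` fronts fast-greedy, walktrap,
leading-eigenvector, louvain, infomap and spin-glass (via igraph) plus the
package's own `spectral_cluster()`: recursive bisection by the leading
eigenvector of the modularity matrix `B_ij = A_ij − k_i k_j / 2m` with
Kernighan–Lin fine-tuning at each split and a global refinement loop.
`modularity_q()`, `normalized_modularity()` (observed Q over the mean Q of
degree-preserving rewired copies), `recluster()` for oversized
communities, `clustering_summary()` and `cluster_layout()` complete the
step.

**Consensus, robustness, bridgeness.** `consensus_matrix()` reruns a
clusterer on random 80% vertex subsamples (500× by default) and records
co-clustering frequencies; `cluster_robustness()` averages them within
clusters; `bridgeness()` turns each vertex's consensus affiliation vector
`p_ic` into `B_i = 1 − sqrt(K/(K−1)) · sqrt(Σ_c (p_ic − 1/K)²)` — 0 for a
vertex firmly in one community, 1 for a global bridge. `influence_table()`
pairs B with any normalised centrality to label local hubs and global
bridges.

**Annotation statistics.** `separation()` computes the disease-module
separation `s_AB = d_AB − (d_AA + d_BB)/2` (negative = topological
overlap); `run_permutation_test()` attaches empirical p-values, Bonferroni
and BH q-values under a term-size-preserving annotation permutation null;
`ora()` runs hypergeometric over-representation of terms in vertex groups;
`intra_class_edges()` tests whether same-class vertices interact more than
label permutation allows. Bipartite (disease–gene) networks are handled by
`build_bipartite()`, `project_bipartite()` and degree-preserving
`rewire_bipartite()`.

Synthetic generators (`planted_partition()`, `power_law_degree_sample()`,
`annotated_planted_graph()`, `toy_diseasome()`) make every stage testable
without external data.

## Worked example

```r
library(bionetkit)

pg  <- planted_partition(n_blocks = 4, block_size = 16,
                         p_in = 0.5, p_out = 0.02, seed = 42)
net <- pg$graph

cl <- cluster_network(net, "spectral")
#> Clustering [spectral]: 4 communities over 64 vertices, Q = 0.6295

clustering_summary(net, list(cl, cluster_network(net, "fc")))
#>   algorithm  N       mod C Cn1 Cn100        mu min_C ... max_C
#> 1  spectral 64 0.6294579 4   0     0 0.1178571    16 ...    16
#> 2        fc 64 0.6294579 4   0     0 0.1178571    16 ...    16

cm <- consensus_matrix(net, "fc", reps = 100, seed = 42)
cluster_robustness(cm, cl)
#>   community size robustness
#> 1         1   16  0.9735667
#> 2         2   16  0.9902514
#> 3         3   16  0.9968716
#> 4         4   16  0.9960194

fit_powerlaw(power_law_degree_sample(2.5, 1, 10000, seed = 42))
#> Discrete power-law fit: alpha = 2.495, xmin = 1, KS = 0.0020 (n_tail = 10000)
```

All four planted blocks are recovered exactly (Q = 0.63, four communities
of 16), the consensus matrix confirms them with robustness above 0.97, and
the power-law fit recovers the generating exponent 2.5 to well within its
sampling error.

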