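test_that("modularity matches the pairwise-sum oracle and known values", {
  # two equal disjoint cliques under the clique partition score exactly 1/2
  g <- build_network(rbind(clique_edges(paste0("a", 1:4)),
                           clique_edges(paste0("b", 1:4))))
  mm <- stats::setNames(rep(1:2, each = 4L), c(paste0("a", 1:4), paste0("b", 1:4)))
  expect_equal(modularity_q(g, mm), 0.5, tolerance = 1e-12)
  expect_equal(modularity_q(g, stats::setNames(rep(1, 8), names(mm))), 0,
               tolerance = 1e-12)

  for (s in 1:6) {
    gr <- random_named_graph(sample(5:10, 1L), 0.4, s + 200L)
    mmr <- sample.int(3L, igraph::vcount(gr), replace = TRUE)
    expect_equal(modularity_q(gr, mmr), brute_modularity(gr, mmr),
                 tolerance = 1e-12)
    # independent library cross-check
    expect_equal(modularity_q(gr, mmr), igraph::modularity(gr, mmr),
                 tolerance = 1e-12)
  }
  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(edgeless)$name <- c("x", "y", "z")
  expect_error(modularity_q(edgeless, c(1, 2, 3)), "no edges")
})

test_that("every algorithm splits two cliques and stores a consistent Q", {
  g <- two_cliques_graph(5L)
  truth <- stats::setNames(rep(1:2, each = 5L),
                           c(paste0("a", 1:5), paste0("b", 1:5)))
  for (alg in c("fc", "wt", "lec", "louvain", "infomap", "sg", "spectral")) {
    cl <- cluster_network(g, alg, seed = 5L)
    expect_equal(cl$n_communities, 2L, info = alg)
    expect_equal(igraph::compare(cl$membership[names(truth)], truth,
                                 method = "nmi"), 1, info = alg)
    expect_equal(cl$modularity, modularity_q(g, cl$membership),
                 tolerance = 1e-9, info = alg)
    expect_equal(sort(unique(unname(cl$membership))),
                 seq_len(cl$n_communities), info = alg)
  }
})

test_that("an edgeless graph clusters into singletons with zero modularity", {
  g <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g)$name <- c("x", "y", "z")
  cl <- cluster_network(g, "fc")
  expect_equal(cl$n_communities, 3L)
  expect_equal(cl$modularity, 0)
})

test_that("deterministic clustering is equivariant under vertex relabelling", {
  g <- random_named_graph(14L, 0.3, 77L)
  cl <- cluster_network(g, "fc")
  perm <- igraph::permute(g, sample(igraph::vcount(g)))
  cl_p <- cluster_network(perm, "fc")
  co <- function(m) outer(m, m, `==`)
  ids <- sort(igraph::V(g)$name)
  expect_equal(co(cl$membership[ids]), co(cl_p$membership[ids]))
})

test_that("spectral clustering is exact on separable graphs and indivisible ones", {
  one <- build_network(clique_edges(paste0("k", 1:5)))
  sc1 <- spectral_cluster(one)
  expect_equal(sc1$n_communities, 1L)
  expect_equal(sc1$modularity, 0)

  g <- two_cliques_graph(4L)
  sc <- spectral_cluster(g)
  expect_equal(sc$n_communities, 2L)
  expect_equal(unname(sc$membership[paste0("a", 1:4)]),
               rep(sc$membership[["a1"]], 4L))

  # near the exhaustive maximum on small graphs; the greedy agglomerative
  # route is allowed a wider slack than the fine-tuned spectral route
  for (s in 1:4) {
    gr <- largest_component(random_named_graph(7L, 0.4, s + 300L))
    qmax <- brute_max_modularity(gr)
    expect_gte(spectral_cluster(gr)$modularity, qmax - 0.05)
    expect_gte(cluster_network(gr, "fc")$modularity, qmax - 0.15)
  }
})

test_that("planted blocks are recovered perfectly at strong contrast", {
  for (s in 1:10) {
    pg <- planted_partition(4L, 16L, 0.5, 0.02, seed = s)
    cl <- spectral_cluster(pg$graph)
    expect_equal(igraph::compare(cl$membership[names(pg$true_membership)],
                                 pg$true_membership, method = "nmi"), 1)
  }
})

test_that("fine-tuning never scores below the plain leading-eigenvector", {
  for (s in 1:25) {
    g <- largest_component(random_named_graph(sample(10:24, 1L), 0.25,
                                              s + 400L))
    q_ft <- spectral_cluster(g, fine_tune = TRUE)$modularity
    q_plain <- spectral_cluster(g, fine_tune = FALSE)$modularity
    q_lec <- cluster_network(g, "lec")$modularity
    expect_gte(q_ft, q_plain - 1e-9)
    expect_gte(q_ft, q_lec - 1e-9)
  }
})

test_that("reclustering splits oversized communities and leaves small ones", {
  g <- two_cliques_graph(5L)
  merged <- new_cl <- cluster_network(g, "fc")
  # force everything into one community, then recluster with threshold 6
  one <- structure(list(algorithm = "fc",
                        membership = stats::setNames(rep(1L, 10L),
                                                     names(merged$membership)),
                        modularity = 0, n_communities = 1L),
                   class = "network_clustering")
  rc <- recluster(g, one, size_threshold = 6L)
  expect_equal(rc$n_communities, 2L)
  expect_equal(sort(unique(unname(rc$membership))), 1:2)

  same <- recluster(g, new_cl, size_threshold = 50L)
  co <- function(m) outer(m, m, `==`)
  ids <- names(new_cl$membership)
  expect_equal(co(same$membership[ids]), co(new_cl$membership[ids]))
})

test_that("clustering summary reports the standard columns", {
  g <- build_network(rbind(clique_edges(paste0("a", 1:4)),
                           clique_edges(paste0("b", 1:4))))
  cl <- cluster_network(g, "fc")
  sm <- clustering_summary(g, cl)
  expect_named(sm, c("algorithm", "N", "mod", "C", "Cn1", "Cn100", "mu",
                     "min_C", "q1_C", "median_C", "mean_C", "q3_C", "max_C"))
  expect_equal(sm$mu, 0)
  expect_equal(sm$C, 2)
  expect_gte(sm$C, sm$Cn1 + sm$Cn100)
  expect_true(sm$min_C <= sm$q1_C && sm$q1_C <= sm$median_C &&
                sm$median_C <= sm$q3_C && sm$q3_C <= sm$max_C)

  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(edgeless)$name <- c("x", "y", "z")
  sm2 <- clustering_summary(edgeless, cluster_network(edgeless, "fc"))
  expect_equal(sm2$C, 3)
  expect_equal(sm2$Cn1, 3)

  # several clusterings stack into one row each
  sm3 <- clustering_summary(g, list(cl, cluster_network(g, "louvain", seed = 1)))
  expect_equal(nrow(sm3), 2L)
})

test_that("normalised modularity separates planted structure from noise", {
  pg <- planted_partition(4L, 12L, 0.6, 0.03, seed = 3)
  cl <- cluster_network(pg$graph, "fc")
  nm <- normalized_modularity(pg$graph, cl, n_rand = 10L, seed = 11)
  expect_gt(nm$q_norm, 1)
  nm2 <- normalized_modularity(pg$graph, cl, n_rand = 10L, seed = 11)
  expect_equal(nm, nm2) # reproducibility contract

  gnp <- largest_component(random_named_graph(48L, 0.1, 91L))
  clr <- cluster_network(gnp, "fc")
  nmr <- normalized_modularity(gnp, clr, n_rand = 10L, seed = 12)
  expect_lt(abs(nmr$q_obs - nmr$null_mean), 2 * nmr$null_sd + 1e-9)
})

test_that("community layout tiles communities into disjoint boxes", {
  g <- two_cliques_graph(5L)
  cl <- cluster_network(g, "fc")
  ly <- cluster_layout(g, cl, seed = 4)
  expect_equal(nrow(ly), igraph::vcount(g))
  boxes <- lapply(split(ly, ly$community), function(d) {
    c(range(d$x), range(d$y))
  })
  expect_true(boxes[[1]][2] < boxes[[2]][1] || boxes[[2]][2] < boxes[[1]][1] ||
                boxes[[1]][4] < boxes[[2]][3] || boxes[[2]][4] < boxes[[1]][3])
  expect_identical(ly, cluster_layout(g, cl, seed = 4))

  single <- build_network(clique_edges(paste0("s", 1:4)))
  expect_equal(nrow(cluster_layout(single, rep(1, 4), seed = 1)), 4L)
})

test_that("community layout scales to a ten-thousand-vertex planted graph", {
  pg <- planted_partition(10L, 1000L, 0.008, 5e-5, seed = 21)
  ly <- cluster_layout(pg$graph, pg$true_membership, seed = 2)
  expect_equal(nrow(ly), 10000L)
  expect_true(all(is.finite(ly$x) & is.finite(ly$y)))
})
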