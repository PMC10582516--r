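# Graph fixtures built in code.

clique_edges <- function(ids) {
  cm <- t(utils::combn(ids, 2L))
  data.frame(a = cm[, 1L], b = cm[, 2L], stringsAsFactors = FALSE)
}

path_edges <- function(ids) {
  data.frame(a = ids[-length(ids)], b = ids[-1L], stringsAsFactors = FALSE)
}

ring_edges <- function(ids) {
  data.frame(a = ids, b = ids[c(2:length(ids), 1L)], stringsAsFactors = FALSE)
}

star_edges <- function(centre = "c", n_leaves = 4L) {
  data.frame(a = rep(centre, n_leaves), b = paste0("l", seq_len(n_leaves)),
             stringsAsFactors = FALSE)
}

# Two cliques of size `k` joined by a single bridge edge a1-b1.
two_cliques_graph <- function(k = 5L) {
  build_network(rbind(clique_edges(paste0("a", seq_len(k))),
                      clique_edges(paste0("b", seq_len(k))),
                      data.frame(a = "a1", b = "b1")))
}

# Small random graph with string names, guaranteed >= 1 edge.
random_named_graph <- function(n, p, seed) {
  g <- bionetkit:::local_seed(seed, igraph::sample_gnp(n, p))
  while (igraph::ecount(g) == 0L) {
    seed <- seed + 1000L
    g <- bionetkit:::local_seed(seed, igraph::sample_gnp(n, p))
  }
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g
}
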