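# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

# Betweenness by exhaustive simple-path enumeration (graphs <= 8 vertices):
# for every vertex pair, list all simple paths by DFS, keep the shortest,
# and credit interior vertices with their share of shortest paths.
brute_betweenness <- function(g) {
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  all_paths <- function(from, to) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == to) {
        out[[length(out) + 1L]] <<- path
        return(invisible(NULL))
      }
      for (nb in adj[[last]]) {
        if (!nb %in% path) walk(c(path, nb))
      }
    }
    walk(from)
    out
  }
  bet <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- all_paths(s, t)
      if (length(paths) == 0L) next
      lens <- vapply(paths, length, 1L)
      short <- paths[lens == min(lens)]
      sigma <- length(short)
      for (p in short) {
        interior <- p[-c(1L, length(p))]
        bet[interior] <- bet[interior] + 1 / sigma
      }
    }
  }
  bet
}

# Modularity by the raw pairwise double sum.
brute_modularity <- function(g, mm) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  k <- igraph::degree(g)
  m2 <- sum(k)
  q <- 0
  n <- length(mm)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (mm[i] == mm[j]) q <- q + A[i, j] - k[i] * k[j] / m2
    }
  }
  unname(q / m2)
}

# All set partitions of n items as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_len(mx + 1L)) grow(c(prefix, v), max(mx, v))
  }
  grow(1L, 1L)
  out
}

# Maximum modularity over every partition (graphs <= 8 vertices).
brute_max_modularity <- function(g) {
  parts <- all_partitions(igraph::vcount(g))
  max(vapply(parts, function(mm) brute_modularity(g, mm), numeric(1L)))
}

# Semi-local centrality straight from its three-step definition.
brute_semi_local <- function(g) {
  n <- igraph::vcount(g)
  D <- igraph::distances(g)
  Nw <- vapply(seq_len(n), function(w) sum(D[w, ] <= 2) - 1L, numeric(1L))
  adj <- igraph::as_adj_list(g, mode = "all")
  Qu <- vapply(seq_len(n), function(u) sum(Nw[as.integer(adj[[u]])]), numeric(1L))
  vapply(seq_len(n), function(v) sum(Qu[as.integer(adj[[v]])]), numeric(1L))
}

# Bridgeness straight from the affiliation formula.
brute_bridgeness <- function(M, mm) {
  K <- length(unique(mm))
  n <- length(mm)
  vapply(seq_len(n), function(i) {
    p <- vapply(sort(unique(mm)), function(c) {
      sum(M[i, setdiff(which(mm == c), i)])
    }, numeric(1L))
    if (sum(p) == 0) p <- rep(1 / K, K) else p <- p / sum(p)
    max(0, min(1, 1 - sqrt(K / (K - 1)) * sqrt(sum((p - 1 / K)^2))))
  }, numeric(1L))
}

# One-sided hypergeometric upper-tail p by direct combinatorial summation.
brute_hyper_p <- function(k, K, n, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Separation statistic via full distance matrices, following the definition
# literally.
brute_separation <- function(g, A, B) {
  ids <- igraph::V(g)$name
  D <- igraph::distances(g)
  rownames(D) <- colnames(D) <- ids
  nn_within <- function(S) {
    v <- vapply(S, function(a) min(D[a, setdiff(S, a)]), numeric(1L))
    mean(v[is.finite(v)])
  }
  nn_between <- function(S1, S2) {
    v <- c(vapply(S1, function(a) min(D[a, S2]), numeric(1L)),
           vapply(S2, function(b) min(D[b, S1]), numeric(1L)))
    mean(v[is.finite(v)])
  }
  nn_between(A, B) - (nn_within(A) + nn_within(B)) / 2
}
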