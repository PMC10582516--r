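# Community detection. Standard algorithms (fast-greedy, walktrap,
# leading-eigenvector, louvain, infomap, spin-glass) are delegated to
# igraph; the fine-tuned spectral bisection is implemented here.

normalize_membership <- function(mm, ids) {
  mm <- as.integer(factor(mm, levels = unique(mm)))
  stats::setNames(mm, ids)
}

new_clustering <- function(net, membership, algorithm) {
  ids <- vertex_ids(net)
  membership <- normalize_membership(membership, ids)
  q <- if (igraph::ecount(net) == 0L) 0 else modularity_q(net, membership)
  structure(
    list(algorithm = algorithm, membership = membership,
         modularity = q, n_communities = max(membership)),
    class = "network_clustering"
  )
}

#' @export
print.network_clustering <- function(x, ...) {
  cat(sprintf("Clustering [%s]: %d communities over %d vertices, Q = %.4f\n",
              x$algorithm, x$n_communities, length(x$membership), x$modularity))
  invisible(x)
}

#' Newman modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(c_i, c_j)`, computed
#' in the equivalent per-community form
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)` where `e_c` counts within-community
#' edges and `d_c` sums community degrees.
#'
#' @param net An `igraph` network with at least one edge.
#' @param membership Community labels: a vector in vertex order or named by
#'   vertex ID.
#' @return Modularity Q (a single number).
#' @export
modularity_q <- function(net, membership) {
  assert_graph(net)
  m <- igraph::ecount(net)
  if (m == 0L) stop("modularity undefined for a graph with no edges", call. = FALSE)
  ids <- vertex_ids(net)
  mm <- if (!is.null(names(membership))) membership[ids] else membership
  if (length(mm) != length(ids) || anyNA(mm)) {
    stop("membership must cover every vertex", call. = FALSE)
  }
  mm <- as.integer(factor(mm))
  el <- igraph::as_edgelist(net, names = FALSE)
  within <- mm[el[, 1L]] == mm[el[, 2L]]
  e_c <- tapply(within, mm[el[, 1L]], sum)
  ec <- numeric(max(mm))
  ec[as.integer(names(e_c))] <- e_c
  deg <- igraph::degree(net)
  d_c <- tapply(deg, mm, sum)
  dc <- numeric(max(mm))
  dc[as.integer(names(d_c))] <- d_c
  sum(ec / m - (dc / (2 * m))^2)
}

#' Detect communities
#'
#' A uniform front end over the modularity/flow-based algorithms commonly
#' applied to PPI networks: fast-greedy (`fc`), walktrap (`wt`),
#' leading-eigenvector (`lec`), louvain, infomap, spin-glass (`sg`, with a
#' configurable spin count), all via igraph, plus the package's own
#' fine-tuned `spectral` bisection ([spectral_cluster()]).
#'
#' A graph with no edges yields all-singleton communities with Q = 0.
#' `fc`, `wt` and `lec` are deterministic; `louvain`, `infomap` and `sg`
#' honour `seed`.
#'
#' @param net A simple undirected `igraph` network.
#' @param algorithm One of `"fc"`, `"wt"`, `"lec"`, `"louvain"`,
#'   `"infomap"`, `"sg"`, `"spectral"`.
#' @param seed Optional integer seed for the stochastic algorithms.
#' @param spins Spin count for `sg` (default 25).
#' @param fine_tune Enable Kernighan-Lin fine-tuning for `spectral`.
#' @return A `network_clustering` object: `algorithm`, `membership` (named,
#'   1-based consecutive), `modularity`, `n_communities`. Has `tidy()` and
#'   `glance()` methods.
#' @export
cluster_network <- function(net, algorithm = c("fc", "wt", "lec", "louvain",
                                               "infomap", "sg", "spectral"),
                            seed = NULL, spins = 25L, fine_tune = TRUE) {
  algorithm <- match.arg(algorithm)
  assert_graph(net)
  net <- ensure_names(net)
  if (igraph::ecount(net) == 0L) {
    return(new_clustering(net, seq_len(igraph::vcount(net)), algorithm))
  }
  if (algorithm == "spectral") {
    return(spectral_cluster(net, fine_tune = fine_tune))
  }
  mem <- local_seed(seed, {
    switch(algorithm,
      fc = igraph::membership(igraph::cluster_fast_greedy(net)),
      wt = igraph::membership(igraph::cluster_walktrap(net)),
      lec = igraph::membership(igraph::cluster_leading_eigen(net)),
      louvain = igraph::membership(igraph::cluster_louvain(net)),
      infomap = igraph::membership(igraph::cluster_infomap(net)),
      sg = {
        # spin-glass requires a connected graph: run per component
        comps <- igraph::components(net)
        mm <- integer(igraph::vcount(net))
        offset <- 0L
        for (ci in seq_len(comps$no)) {
          vs <- which(comps$membership == ci)
          if (length(vs) == 1L) {
            mm[vs] <- offset + 1L
            offset <- offset + 1L
          } else {
            sub <- igraph::induced_subgraph(net, vs)
            cm <- igraph::membership(igraph::cluster_spinglass(sub, spins = spins))
            mm[vs] <- offset + as.integer(cm)
            offset <- offset + max(cm)
          }
        }
        mm
      }
    )
  })
  new_clustering(net, as.integer(mem), algorithm)
}

# Kernighan-Lin style refinement of a +/-1 split vector s against the
# (generalised) modularity matrix Bg, maximising s' Bg s. Each sweep moves
# every vertex at most once, keeps the best visited prefix, and sweeps
# repeat until no improvement. Returns the refined s.
kl_refine <- function(Bg, s, tol = 1e-9) {
  n <- length(s)
  dg <- diag(Bg)
  repeat {
    g <- as.numeric(Bg %*% s)
    moved <- rep(FALSE, n)
    states <- matrix(0L, nrow = n, ncol = 0L)
    cumgain <- numeric(0L)
    s_work <- s
    total <- 0
    for (step in seq_len(n)) {
      gains <- -4 * s_work * g + 4 * dg
      gains[moved] <- -Inf
      i <- which.max(gains)
      total <- total + gains[i]
      g <- g - 2 * s_work[i] * Bg[, i]
      s_work[i] <- -s_work[i]
      moved[i] <- TRUE
      cumgain <- c(cumgain, total)
      states <- cbind(states, s_work)
    }
    best <- which.max(cumgain)
    if (cumgain[best] > tol) {
      s <- states[, best]
    } else {
      return(s)
    }
  }
}

#' Spectral community detection with fine-tuning
#'
#' Recursive bisection by the leading eigenvector of the modularity matrix
#' `B_ij = A_ij - k_i k_j / 2m` (using the generalised matrix
#' `B^(g)_ij = B_ij - delta_ij * sum_{k in g} B_ik` for subdivisions).
#' After each proposed split a Kernighan-Lin fine-tuning stage sweeps over
#' the vertices, moving each at most once per sweep and keeping the best
#' visited state, repeating until no sweep improves Q. Recursion stops when
#' the leading eigenvalue falls below tolerance or the proposed split does
#' not increase Q. A final single-vertex relocation pass between arbitrary
#' communities runs while it strictly increases Q, so fine-tuned results
#' are never worse than the plain eigenvector split.
#'
#' Disconnected inputs are handled per component.
#'
#' @param net A simple undirected `igraph` network.
#' @param fine_tune Enable the fine-tuning stages (default `TRUE`).
#' @param tol Tolerance on eigenvalues and modularity gains.
#' @return A `network_clustering` with `algorithm = "spectral"`.
#' @export
spectral_cluster <- function(net, fine_tune = TRUE, tol = 1e-9) {
  assert_graph(net)
  net <- ensure_names(net)
  n <- igraph::vcount(net)
  if (igraph::ecount(net) == 0L) {
    return(new_clustering(net, seq_len(n), "spectral"))
  }
  comps <- igraph::components(net)
  mm <- integer(n)
  offset <- 0L
  for (ci in seq_len(comps$no)) {
    vs <- which(comps$membership == ci)
    if (length(vs) == 1L || igraph::ecount(igraph::induced_subgraph(net, vs)) == 0L) {
      mm[vs] <- offset + 1L
      offset <- offset + 1L
      next
    }
    sub <- igraph::induced_subgraph(net, vs)
    sub_mm <- spectral_component(sub, fine_tune = fine_tune, tol = tol)
    mm[vs] <- offset + sub_mm
    offset <- offset + max(sub_mm)
  }
  new_clustering(net, mm, "spectral")
}

spectral_component <- function(net, fine_tune, tol) {
  if (!fine_tune) return(spectral_bisect(net, kl = FALSE, tol = tol))
  # The per-split refinement can occasionally steer the recursion towards a
  # worse stopping point than the plain split would reach, so both recursion
  # variants are run, each is polished by the global refinement loop, and
  # the higher-modularity partition is kept ("best visited state" at the
  # level of the whole recursion tree).
  cands <- list(spectral_bisect(net, kl = TRUE, tol = tol),
                spectral_bisect(net, kl = FALSE, tol = tol))
  cands <- lapply(cands, function(mm) {
    if (max(mm) < 2L) return(mm)
    repeat {
      mm2 <- kl_partition_refine(net, mm, tol = tol)
      mm2 <- merge_refine(net, mm2, tol = tol)
      if (identical(mm2, mm)) break
      mm <- mm2
    }
    mm
  })
  qs <- vapply(cands, function(mm) {
    if (max(mm) < 2L || igraph::ecount(net) == 0L) 0 else modularity_q(net, mm)
  }, numeric(1L))
  cands[[which.max(qs)]]
}

spectral_bisect <- function(net, kl, tol) {
  n <- igraph::vcount(net)
  A <- as.matrix(igraph::as_adjacency_matrix(net))
  k <- igraph::degree(net)
  m2 <- sum(k) # 2m
  B <- A - outer(k, k) / m2
  groups <- list()
  split_group <- function(idx) {
    if (length(idx) < 2L) {
      groups[[length(groups) + 1L]] <<- idx
      return(invisible(NULL))
    }
    Bsub <- B[idx, idx, drop = FALSE]
    Bg <- Bsub
    diag(Bg) <- diag(Bsub) - rowSums(Bsub)
    es <- eigen(Bg, symmetric = TRUE)
    if (es$values[1L] <= tol) {
      groups[[length(groups) + 1L]] <<- idx
      return(invisible(NULL))
    }
    v <- es$vectors[, 1L]
    s <- ifelse(v >= 0, 1, -1)
    if (kl) s <- kl_refine(Bg, s, tol = tol)
    dq <- as.numeric(t(s) %*% Bg %*% s) / (2 * m2)
    if (dq <= tol || all(s == s[1L])) {
      groups[[length(groups) + 1L]] <<- idx
      return(invisible(NULL))
    }
    split_group(idx[s > 0])
    split_group(idx[s < 0])
  }
  split_group(seq_len(n))
  mm <- integer(n)
  for (gi in seq_along(groups)) mm[groups[[gi]]] <- gi
  # order community indices by first appearance for determinism
  as.integer(factor(mm, levels = unique(mm)))
}

# Merge community pairs while doing so increases modularity. The gain of
# merging c and d is e_cd / m - d_c d_d / (2 m^2).
merge_refine <- function(net, mm, tol = 1e-9) {
  m <- igraph::ecount(net)
  deg <- igraph::degree(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  repeat {
    nc <- max(mm)
    if (nc < 2L) break
    d_c <- vapply(seq_len(nc), function(c) sum(deg[mm == c]), numeric(1L))
    e_cd <- matrix(0, nc, nc)
    for (e in seq_len(nrow(el))) {
      c1 <- mm[el[e, 1L]]; c2 <- mm[el[e, 2L]]
      if (c1 != c2) {
        e_cd[c1, c2] <- e_cd[c1, c2] + 1
        e_cd[c2, c1] <- e_cd[c2, c1] + 1
      }
    }
    gain <- e_cd / m - outer(d_c, d_c) / (2 * m^2)
    diag(gain) <- -Inf
    best <- which.max(gain)
    if (gain[best] <= tol) break
    i <- ((best - 1L) %% nc) + 1L
    j <- ((best - 1L) %/% nc) + 1L
    mm[mm == max(i, j)] <- min(i, j)
    mm <- as.integer(factor(mm, levels = sort(unique(mm))))
  }
  as.integer(factor(mm, levels = unique(mm)))
}

# Kernighan-Lin refinement over a full multi-community partition: in each
# sweep every vertex is moved at most once, to its best alternative
# community (taking the best available move even when its immediate gain is
# negative), the best visited partition prefix is kept, and sweeps repeat
# until none improves Q.
kl_partition_refine <- function(net, mm, tol = 1e-9) {
  m <- igraph::ecount(net)
  deg <- igraph::degree(net)
  adj <- igraph::as_adj_list(net, mode = "all")
  n <- length(mm)
  nc <- max(mm)
  repeat {
    d_c <- vapply(seq_len(nc), function(c) sum(deg[mm == c]), numeric(1L))
    cur <- mm
    moved <- rep(FALSE, n)
    total <- 0
    best_gain <- 0
    best_state <- mm
    for (step in seq_len(n)) {
      step_best <- -Inf
      step_v <- 0L
      step_c <- 0L
      for (v in which(!moved)) {
        cv <- cur[v]
        e_to <- tabulate(cur[adj[[v]]], nbins = nc)
        base <- e_to[cv] / m - deg[v] * (d_c[cv] - deg[v]) / (2 * m^2)
        gains <- e_to / m - deg[v] * d_c / (2 * m^2) - base
        gains[cv] <- -Inf
        c2 <- which.max(gains)
        if (gains[c2] > step_best) {
          step_best <- gains[c2]
          step_v <- v
          step_c <- c2
        }
      }
      if (step_v == 0L) break
      cv <- cur[step_v]
      d_c[cv] <- d_c[cv] - deg[step_v]
      d_c[step_c] <- d_c[step_c] + deg[step_v]
      cur[step_v] <- step_c
      moved[step_v] <- TRUE
      total <- total + step_best
      if (total > best_gain) {
        best_gain <- total
        best_state <- cur
      }
    }
    if (best_gain > tol) {
      mm <- best_state
    } else {
      break
    }
  }
  as.integer(factor(mm, levels = unique(mm)))
}

# Greedy single-vertex relocation between arbitrary communities while the
# modularity strictly increases. Ties broken by lowest vertex then lowest
# target community index.
relocate_refine <- function(net, mm, tol = 1e-9) {
  m <- igraph::ecount(net)
  deg <- igraph::degree(net)
  adj <- igraph::as_adj_list(net, mode = "all")
  nc <- max(mm)
  d_c <- vapply(seq_len(nc), function(c) sum(deg[mm == c]), numeric(1L))
  repeat {
    improved <- FALSE
    for (v in seq_along(mm)) {
      cv <- mm[v]
      nb <- adj[[v]]
      # edges from v into each community
      e_to <- tabulate(mm[nb], nbins = nc)
      base <- e_to[cv] / m - deg[v] * (d_c[cv] - deg[v]) / (2 * m^2)
      gains <- e_to / m - deg[v] * d_c / (2 * m^2) - base
      gains[cv] <- 0
      best <- which.max(gains)
      if (gains[best] > tol) {
        d_c[cv] <- d_c[cv] - deg[v]
        d_c[best] <- d_c[best] + deg[v]
        mm[v] <- best
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  as.integer(factor(mm, levels = unique(mm)))
}

#' Normalised modularity
#'
#' Divides the observed modularity by the mean modularity achieved on
#' degree-preserving randomised copies of the network, each clustered with
#' the same algorithm. Values near 1 indicate no more community structure
#' than expected from the degree sequence alone; values above 1 indicate
#' genuine structure. Enables comparison across networks of different size
#' and density.
#'
#' @param net An `igraph` network.
#' @param clustering A `network_clustering` for `net`.
#' @param n_rand Number of rewired replicates (>= 10).
#' @param seed Optional integer seed.
#' @param spins Spin count forwarded to `sg`.
#' @return A one-row tibble: `q_norm`, `q_obs`, `null_mean`, `null_sd`,
#'   `n_rand`.
#' @export
normalized_modularity <- function(net, clustering, n_rand = 10L, seed = NULL,
                                  spins = 25L) {
  assert_graph(net)
  if (!inherits(clustering, "network_clustering")) {
    stop("`clustering` must be a network_clustering object", call. = FALSE)
  }
  if (is.null(clustering$algorithm)) stop("clustering lacks an algorithm label",
                                          call. = FALSE)
  stopifnot(n_rand >= 10L)
  q_null <- vapply(seq_len(n_rand), function(r) {
    g2 <- local_seed(derive_seed(seed, r),
                     igraph::rewire(net, igraph::keeping_degseq(
                       niter = 10L * igraph::ecount(net))))
    cluster_network(g2, clustering$algorithm, seed = derive_seed(seed, r + n_rand),
                    spins = spins)$modularity
  }, numeric(1L))
  tibble::tibble(
    q_norm = clustering$modularity / mean(q_null),
    q_obs = clustering$modularity,
    null_mean = mean(q_null),
    null_sd = stats::sd(q_null),
    n_rand = as.integer(n_rand)
  )
}

#' Hierarchically re-cluster oversized communities
#'
#' Large "super"-communities mask substructure. Every community larger than
#' `size_threshold` is replaced by the communities found by running
#' `algorithm` on its induced subgraph; indices are renumbered
#' consecutively. With `recurse = TRUE` passes repeat until no community
#' exceeds the threshold or a pass changes nothing.
#'
#' @param net An `igraph` network.
#' @param clustering A `network_clustering` for `net`.
#' @param size_threshold Communities larger than this are split (>= 2).
#' @param algorithm Algorithm for the sub-clustering (defaults to the one in
#'   `clustering`).
#' @param seed Optional integer seed.
#' @param recurse Repeat until stable (default `FALSE`: one pass).
#' @param spins Spin count forwarded to `sg`.
#' @return A new `network_clustering`.
#' @export
recluster <- function(net, clustering, size_threshold, algorithm = NULL,
                      seed = NULL, recurse = FALSE, spins = 25L) {
  assert_graph(net)
  stopifnot(size_threshold >= 2L)
  algorithm <- algorithm %||% clustering$algorithm
  ids <- vertex_ids(net)
  mm <- clustering$membership[ids]
  pass <- 0L
  repeat {
    pass <- pass + 1L
    sizes <- table(mm)
    big <- as.integer(names(sizes)[sizes > size_threshold])
    if (length(big) == 0L) break
    changed <- FALSE
    nxt <- max(mm)
    for (c in big) {
      vs <- which(mm == c)
      sub <- igraph::induced_subgraph(net, vs)
      subcl <- cluster_network(sub, algorithm, seed = derive_seed(seed, pass * 1000L + c),
                               spins = spins)
      smm <- subcl$membership[vertex_ids(sub)]
      if (max(smm) > 1L) changed <- TRUE
      mm[vs] <- nxt + as.integer(smm)
      nxt <- nxt + max(smm)
    }
    mm <- as.integer(factor(mm, levels = unique(mm)))
    names(mm) <- ids
    if (!recurse || !changed) break
  }
  out <- new_clustering(net, mm, algorithm)
  out
}

#' Summarise one or more clusterings
#'
#' One row per clustering with the standard comparison columns: vertex
#' count `N`, modularity `mod`, community count `C`, singleton count `Cn1`,
#' number of communities at or above `big_size` (`Cn100`, threshold 100 by
#' default), the fraction of edges lying between communities (`mu`), and
#' the quartile summary of community sizes.
#'
#' @param net An `igraph` network.
#' @param clusterings A `network_clustering` or a list of them.
#' @param big_size Size threshold for the `Cn100` column (default 100).
#' @return A tibble with columns `algorithm`, `N`, `mod`, `C`, `Cn1`,
#'   `Cn100`, `mu`, `min_C`, `q1_C`, `median_C`, `mean_C`, `q3_C`, `max_C`.
#' @export
clustering_summary <- function(net, clusterings, big_size = 100L) {
  assert_graph(net)
  if (inherits(clusterings, "network_clustering")) clusterings <- list(clusterings)
  ids <- vertex_ids(net)
  el <- igraph::as_edgelist(net, names = TRUE)
  m <- nrow(el)
  rows <- lapply(clusterings, function(cl) {
    mm <- cl$membership[ids]
    sizes <- as.numeric(table(mm))
    mu <- if (m == 0L) 0 else mean(mm[el[, 1L]] != mm[el[, 2L]])
    qs <- stats::quantile(sizes, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    tibble::tibble(
      algorithm = cl$algorithm,
      N = length(ids),
      mod = cl$modularity,
      C = length(sizes),
      Cn1 = sum(sizes == 1),
      Cn100 = sum(sizes >= big_size),
      mu = mu,
      min_C = qs[1L], q1_C = qs[2L], median_C = qs[3L],
      mean_C = mean(sizes), q3_C = qs[4L], max_C = qs[5L]
    )
  })
  dplyr::bind_rows(rows)
}

#' Community-aware graph layout
#'
#' Lays out each community independently with the Fruchterman-Reingold
#' force-directed method, then places the per-community layouts on a
#' non-overlapping grid, cells sorted by community size (largest first) and
#' scaled with the square root of community size. Deterministic given
#' `seed`; scales to very large graphs because the force-directed step only
#' ever sees one community at a time.
#'
#' @param net An `igraph` network.
#' @param membership Community labels (vector in vertex order or named).
#' @param seed Optional integer seed.
#' @return A tibble `vertex_id`, `community`, `x`, `y`.
#' @export
cluster_layout <- function(net, membership, seed = NULL) {
  assert_graph(net)
  net <- ensure_names(net)
  ids <- vertex_ids(net)
  if (inherits(membership, "network_clustering")) membership <- membership$membership
  mm <- if (!is.null(names(membership))) membership[ids] else membership
  if (length(mm) != length(ids) || anyNA(mm)) {
    stop("membership must cover every vertex", call. = FALSE)
  }
  mm <- as.integer(factor(mm))
  comms <- sort(unique(mm))
  sizes <- tabulate(mm)
  ord <- order(sizes[comms], decreasing = TRUE)
  ncols <- ceiling(sqrt(length(comms)))
  coords <- matrix(0, nrow = length(ids), ncol = 2L)
  local_seed(seed, {
    for (pos in seq_along(ord)) {
      c <- comms[ord[pos]]
      vs <- which(mm == c)
      sub <- igraph::induced_subgraph(net, vs)
      xy <- igraph::layout_with_fr(sub)
      # normalise into the unit box (degenerate layouts collapse to centre)
      rng_x <- range(xy[, 1L]); rng_y <- range(xy[, 2L])
      xy[, 1L] <- if (diff(rng_x) > 0) (xy[, 1L] - rng_x[1L]) / diff(rng_x) else 0.5
      xy[, 2L] <- if (diff(rng_y) > 0) (xy[, 2L] - rng_y[1L]) / diff(rng_y) else 0.5
      side <- sqrt(length(vs)) # cell scale grows with community size
      row <- (pos - 1L) %/% ncols
      col <- (pos - 1L) %% ncols
      cell <- max(sqrt(sizes)) * 1.5
      coords[vs, 1L] <- col * cell + xy[, 1L] * side
      coords[vs, 2L] <- row * cell + xy[, 2L] * side
    }
  })
  tibble::tibble(vertex_id = ids, community = mm,
                 x = coords[, 1L], y = coords[, 2L])
}
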