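#' Vertex centrality matrix
#'
#' Computes the seven standard per-vertex topology measures used throughout
#' the pipeline: degree (`DEG`), betweenness (`BET`, raw pair counts),
#' local clustering coefficient (`CC`, 0 for degree < 2 vertices),
#' normalised semi-local centrality (`SL`), mean (`mnSP`) and standard
#' deviation (`sdSP`) of the shortest-path length to reachable vertices,
#' and PageRank (`PR`, damping 0.85).
#'
#' Shortest-path statistics are computed within connected components:
#' unreachable pairs are excluded. The output is deterministic.
#'
#' @param net An `igraph` network.
#' @return A tibble with columns `vertex_id`, `DEG`, `BET`, `CC`, `SL`,
#'   `mnSP`, `PR`, `sdSP`.
#' @export
calc_centrality <- function(net) {
  assert_graph(net)
  net <- ensure_names(net)
  ids <- vertex_ids(net)
  deg <- igraph::degree(net)
  bet <- igraph::betweenness(net, normalized = FALSE)
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  cc[deg < 2L] <- 0
  pr <- igraph::page_rank(net, damping = 0.85)$vector
  d <- igraph::distances(net)
  diag(d) <- Inf # self excluded from path statistics
  fin <- is.finite(d)
  mnsp <- vapply(seq_len(nrow(d)), function(i) {
    x <- d[i, fin[i, ]]
    if (length(x) == 0L) 0 else mean(x)
  }, numeric(1L))
  sdsp <- vapply(seq_len(nrow(d)), function(i) {
    x <- d[i, fin[i, ]]
    if (length(x) < 2L) 0 else stats::sd(x)
  }, numeric(1L))
  sl <- semi_local_centrality(net, normalize = TRUE)
  tibble::tibble(
    vertex_id = ids,
    DEG = as.integer(deg),
    BET = unname(bet),
    CC = unname(cc),
    SL = unname(sl),
    mnSP = mnsp,
    PR = unname(pr),
    sdSP = sdsp
  )
}

#' Semi-local centrality
#'
#' A two-hop influence measure. With `N(w)` the number of distinct vertices
#' within distance two of `w` (excluding `w` itself), `Q(u) = sum of N(w)`
#' over the neighbours `w` of `u`, and the semi-local centrality of `v` is
#' `CL(v) = sum of Q(u)` over the neighbours `u` of `v`. With
#' `normalize = TRUE` values are divided by the maximum `CL` so they lie in
#' `[0, 1]` with at least one vertex at 1.
#'
#' @param net An `igraph` network.
#' @param normalize Divide by the maximum value (default `TRUE`).
#' @return A named numeric vector over vertices. Isolated vertices score 0.
#' @export
semi_local_centrality <- function(net, normalize = TRUE) {
  assert_graph(net)
  ids <- vertex_ids(net)
  n2 <- igraph::ego_size(net, order = 2L, mindist = 1L) # within distance <= 2, self excluded
  adj <- igraph::as_adj_list(net, mode = "all")
  q <- vapply(adj, function(nb) sum(n2[nb]), numeric(1L))
  cl <- vapply(adj, function(nb) sum(q[nb]), numeric(1L))
  if (normalize) {
    mx <- max(cl)
    if (mx > 0) cl <- cl / mx
  }
  stats::setNames(cl, ids)
}

#' Generate a randomised graph
#'
#' Three null models for comparing an observed network against chance
#' expectation: `gnp` (Erdos-Renyi G(n, p)), `barabasi_albert` (preferential
#' attachment with `m` edges per new vertex), and `perturb` (copy a template
#' graph, then iteratively add `n_add` random non-edges and remove
#' `n_remove` random edges).
#'
#' @param model `"gnp"`, `"barabasi_albert"` or `"perturb"`.
#' @param n,p G(n, p) parameters.
#' @param m Barabasi-Albert edges per step (requires `m < n`).
#' @param template Template graph for `perturb`.
#' @param n_add,n_remove Edge additions/removals for `perturb`.
#' @param seed Optional integer seed.
#' @return An undirected `igraph` network.
#' @export
random_graph <- function(model = c("gnp", "barabasi_albert", "perturb"),
                         n = NULL, p = NULL, m = NULL, template = NULL,
                         n_add = 0L, n_remove = 0L, seed = NULL) {
  model <- match.arg(model)
  local_seed(seed, {
    out <- switch(model,
      gnp = {
        stopifnot(!is.null(n), !is.null(p))
        if (p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
        igraph::sample_gnp(n, p, directed = FALSE)
      },
      barabasi_albert = {
        stopifnot(!is.null(n), !is.null(m))
        if (m >= n) stop("barabasi_albert requires m < n", call. = FALSE)
        igraph::sample_pa(n, m = m, directed = FALSE)
      },
      perturb = {
        if (is.null(template)) stop("perturb requires a template graph", call. = FALSE)
        g <- ensure_names(template)
        nn <- igraph::vcount(g)
        for (i in seq_len(n_add)) {
          non <- which(!as.matrix(igraph::as_adjacency_matrix(g)) &
                         upper.tri(matrix(TRUE, nn, nn)))
          if (length(non) == 0L) break
          pickl <- sample(non, 1L)
          i1 <- ((pickl - 1L) %% nn) + 1L
          j1 <- ((pickl - 1L) %/% nn) + 1L
          g <- igraph::add_edges(g, c(i1, j1))
        }
        for (i in seq_len(n_remove)) {
          if (igraph::ecount(g) == 0L) break
          g <- igraph::delete_edges(g, sample.int(igraph::ecount(g), 1L))
        }
        g
      }
    )
    ensure_names(out)
  })
}

#' Compare observed centrality to a randomised-graph null
#'
#' Generates `n_reps` random graphs matched on vertex and edge counts,
#' computes the chosen centrality on each, and summarises the null
#' distribution per vertex rank (values sorted in decreasing order), next to
#' the observed sorted values.
#'
#' @param net Observed network.
#' @param measure A [calc_centrality()] column name, e.g. `"DEG"`.
#' @param model Null model label as in [random_graph()].
#' @param n_reps Number of null replicates (>= 1).
#' @param n_add,n_remove Perturbation sizes when `model = "perturb"`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `rank`, `observed`, `null_mean`, `null_sd`.
#' @export
compare_to_random <- function(net, measure = "DEG",
                              model = c("gnp", "barabasi_albert", "perturb"),
                              n_reps = 100L, n_add = 0L, n_remove = 0L,
                              seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_reps >= 1L)
  cm <- calc_centrality(net)
  if (!measure %in% names(cm)[-1L]) {
    stop(sprintf("unknown measure '%s'", measure), call. = FALSE)
  }
  obs <- sort(cm[[measure]], decreasing = TRUE)
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  nulls <- matrix(NA_real_, nrow = n_reps, ncol = n)
  for (r in seq_len(n_reps)) {
    g <- switch(model,
      gnp = random_graph("gnp", n = n, p = m / choose(n, 2),
                         seed = derive_seed(seed, r)),
      barabasi_albert = random_graph("barabasi_albert", n = n,
                                     m = max(1L, round(m / n)),
                                     seed = derive_seed(seed, r)),
      perturb = random_graph("perturb", template = net, n_add = n_add,
                             n_remove = n_remove, seed = derive_seed(seed, r))
    )
    v <- calc_centrality(g)[[measure]]
    v <- sort(v, decreasing = TRUE)
    length(v) <- n
    nulls[r, ] <- v
  }
  tibble::tibble(
    rank = seq_len(n),
    observed = obs,
    null_mean = colMeans(nulls, na.rm = TRUE),
    null_sd = apply(nulls, 2L, stats::sd, na.rm = TRUE)
  )
}
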