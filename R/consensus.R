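#' Consensus matrix by resampled clustering
#'
#' Repeatedly samples a proportion of the vertices (80% by default),
#' clusters the induced subgraph, and records how often each vertex pair
#' lands in the same community. Entry `M[i, j]` is the number of runs
#' placing `i` and `j` together divided by the number of runs sampling both
#' (so subsampling does not bias the frequencies downward); pairs never
#' co-sampled get 0 and their count is reported in a message. Per-replicate
#' seeds are derived from the master seed by a counter scheme, so results
#' are reproducible.
#'
#' @param net An `igraph` network.
#' @param algorithm Clustering algorithm label (see [cluster_network()]).
#' @param sample_fraction Proportion of vertices per replicate, in (0, 1].
#' @param reps Number of replicates (>= 1; 500 by default).
#' @param seed Optional master seed.
#' @param spins Spin count forwarded to `sg`.
#' @return An object of class `consensus_matrix`: list with the symmetric
#'   matrix `M` (vertex IDs as dimnames), `vertices`, `algorithm`,
#'   `sample_fraction`, `reps`, `seed`.
#' @export
consensus_matrix <- function(net, algorithm = "fc", sample_fraction = 0.8,
                             reps = 500L, seed = NULL, spins = 25L) {
  assert_graph(net)
  net <- ensure_names(net)
  if (sample_fraction <= 0 || sample_fraction > 1) {
    stop("sample_fraction must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(reps >= 1L)
  n <- igraph::vcount(net)
  ids <- vertex_ids(net)
  n_take <- max(2L, floor(sample_fraction * n))
  together <- matrix(0, n, n)
  co_sampled <- matrix(0, n, n)
  for (r in seq_len(reps)) {
    vs <- if (n_take >= n) seq_len(n) else {
      local_seed(derive_seed(seed, 2L * r), sort(sample.int(n, n_take)))
    }
    sub <- igraph::induced_subgraph(net, vs)
    cl <- cluster_network(sub, algorithm, seed = derive_seed(seed, 2L * r + 1L),
                          spins = spins)
    mm <- unname(cl$membership[vertex_ids(sub)])
    co_sampled[vs, vs] <- co_sampled[vs, vs] + 1
    same <- outer(mm, mm, `==`)
    together[vs, vs] <- together[vs, vs] + same
  }
  M <- ifelse(co_sampled > 0, together / pmax(co_sampled, 1), 0)
  never <- sum(co_sampled[upper.tri(co_sampled)] == 0)
  if (never > 0L) {
    message(sprintf("consensus_matrix: %d vertex pair(s) never co-sampled", never))
  }
  dimnames(M) <- list(ids, ids)
  structure(
    list(M = M, vertices = ids, algorithm = algorithm,
         sample_fraction = sample_fraction, reps = as.integer(reps), seed = seed),
    class = "consensus_matrix"
  )
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat(sprintf("Consensus matrix [%s]: %d vertices, %d reps at %.0f%% sampling\n",
              x$algorithm, length(x$vertices), x$reps, 100 * x$sample_fraction))
  invisible(x)
}

check_cm_clustering <- function(cm, clustering) {
  if (!inherits(cm, "consensus_matrix")) {
    stop("`cm` must be a consensus_matrix", call. = FALSE)
  }
  mem <- if (inherits(clustering, "network_clustering")) {
    clustering$membership
  } else {
    clustering
  }
  if (is.null(names(mem)) || !setequal(names(mem), cm$vertices)) {
    stop("clustering vertices do not match the consensus matrix", call. = FALSE)
  }
  as.integer(mem[cm$vertices])
}

#' Per-cluster robustness from a consensus matrix
#'
#' For each cluster, the mean consensus value over its unordered within-
#' cluster vertex pairs: near 1 when resampled runs keep reuniting the
#' cluster (high confidence it exists), near 0 when they do not. Singleton
#' clusters score 1 by convention (no pairs to disagree).
#'
#' @param cm A [consensus_matrix()].
#' @param clustering A `network_clustering` (or named membership vector)
#'   over the same vertices.
#' @return A tibble `community`, `size`, `robustness`.
#' @export
cluster_robustness <- function(cm, clustering) {
  mm <- check_cm_clustering(cm, clustering)
  comms <- sort(unique(mm))
  rows <- lapply(comms, function(c) {
    vs <- which(mm == c)
    rob <- if (length(vs) < 2L) 1 else {
      sub <- cm$M[vs, vs, drop = FALSE]
      mean(sub[upper.tri(sub)])
    }
    tibble::tibble(community = c, size = length(vs), robustness = rob)
  })
  dplyr::bind_rows(rows)
}

#' Per-vertex bridgeness
#'
#' Measures how evenly a vertex's consensus co-clustering mass spreads over
#' the communities of a reference clustering. The affiliation of vertex `i`
#' with community `c` is `p_ic`, the sum of consensus entries `M[i, j]`
#' over the members `j != i` of `c`, renormalised so the affiliations sum
#' to 1 (an all-zero row gets the uniform affiliation). Bridgeness is then
#' `B_i = 1 - sqrt(K / (K - 1)) * sqrt(sum_c (p_ic - 1/K)^2)`:
#' 0 when the vertex belongs clearly to a single community, 1 when it
#' bridges all `K` communities with equal strength.
#'
#' @param cm A [consensus_matrix()].
#' @param clustering Reference clustering with at least 2 communities.
#' @return A tibble of class `bridgeness_table`: `vertex_id`, `community`,
#'   `bridgeness`.
#' @export
bridgeness <- function(cm, clustering) {
  mm <- check_cm_clustering(cm, clustering)
  K <- length(unique(mm))
  if (K < 2L) stop("bridgeness undefined for a single community", call. = FALSE)
  n <- length(mm)
  M <- cm$M
  diag(M) <- 0
  # column-sum M over community blocks: n x K affiliation mass
  mass <- sapply(sort(unique(mm)), function(c) rowSums(M[, mm == c, drop = FALSE]))
  tot <- rowSums(mass)
  p <- mass / ifelse(tot > 0, tot, 1)
  p[tot == 0, ] <- 1 / K
  b <- 1 - sqrt(K / (K - 1)) * sqrt(rowSums((p - 1 / K)^2))
  b <- pmin(pmax(b, 0), 1)
  out <- tibble::tibble(vertex_id = cm$vertices, community = mm,
                        bridgeness = unname(b))
  class(out) <- c("bridgeness_table", class(out))
  out
}

#' Pair bridgeness with a normalised centrality for influence plots
#'
#' Joins bridgeness with any normalised (values in `[0, 1]`) vertex
#' centrality, e.g. semi-local centrality, and labels each vertex's
#' influence quadrant at the given thresholds: high bridgeness / low
#' centrality = `"global bridge"`, low/high = `"local hub"`, high/high =
#' `"bridging hub"`, low/low = `"peripheral"`.
#'
#' @param bt A [bridgeness()] table.
#' @param centrality Named numeric vector (or tibble `vertex_id`, value) in
#'   `[0, 1]` over the same vertices.
#' @param thresholds Length-2 numeric: bridgeness and centrality cutoffs
#'   (default `c(0.5, 0.5)`).
#' @return A tibble `vertex_id`, `bridgeness`, `centrality`, `quadrant`.
#' @export
influence_table <- function(bt, centrality, thresholds = c(0.5, 0.5)) {
  if (!inherits(bt, "bridgeness_table")) {
    stop("`bt` must come from bridgeness()", call. = FALSE)
  }
  if (is.data.frame(centrality)) {
    centrality <- stats::setNames(centrality[[2L]], centrality[[1L]])
  }
  if (is.null(names(centrality)) || !setequal(names(centrality), bt$vertex_id)) {
    stop("centrality must be named over the same vertex set", call. = FALSE)
  }
  cv <- unname(centrality[bt$vertex_id])
  if (any(cv < 0 | cv > 1, na.rm = TRUE)) {
    stop("centrality must be normalised to [0, 1]", call. = FALSE)
  }
  hiB <- bt$bridgeness >= thresholds[1L]
  hiC <- cv >= thresholds[2L]
  quadrant <- dplyr::case_when(
    hiB & !hiC ~ "global bridge",
    !hiB & hiC ~ "local hub",
    hiB & hiC ~ "bridging hub",
    TRUE ~ "peripheral"
  )
  tibble::tibble(vertex_id = bt$vertex_id, bridgeness = bt$bridgeness,
                 centrality = cv, quadrant = quadrant)
}
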