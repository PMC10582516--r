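# Annotation-set localisation statistics (disease-module style overlap /
# separation), permutation significance, over-representation analysis and
# intra-class edge enrichment.

# Extract term -> vertex sets from a semicolon-separated vertex attribute.
attr_term_sets <- function(net, attr_name) {
  vals <- igraph::vertex_attr(net, attr_name)
  if (is.null(vals)) stop(sprintf("vertex attribute '%s' not found", attr_name),
                          call. = FALSE)
  ids <- vertex_ids(net)
  terms <- strsplit(ifelse(is.na(vals), "", vals), ";", fixed = TRUE)
  long <- data.frame(
    vertex_id = rep(ids, lengths(terms)),
    term = unlist(terms),
    stringsAsFactors = FALSE
  )
  long <- long[nzchar(long$term), , drop = FALSE]
  split(long$vertex_id, long$term)
}

# Mean-distance statistics for vertex index sets on a precomputed distance
# matrix D. Within: mean over members of the distance to the nearest other
# member. Between: mean over all members of both sets of the distance to
# the nearest member of the opposite set (members of both sets sit at
# distance 0). Unreachable (infinite) terms are dropped and counted.
set_dist_within <- function(D, idx) {
  if (length(idx) < 2L) stop("within-set distance needs at least 2 members",
                             call. = FALSE)
  sub <- D[idx, idx, drop = FALSE]
  diag(sub) <- Inf
  nn <- apply(sub, 1L, min)
  fin <- is.finite(nn)
  if (!any(fin)) stop("no finite distances", call. = FALSE)
  structure(mean(nn[fin]), dropped = sum(!fin))
}

set_dist_between <- function(D, idxA, idxB) {
  nnA <- apply(D[idxA, idxB, drop = FALSE], 1L, min)
  nnB <- apply(D[idxB, idxA, drop = FALSE], 1L, min)
  nn <- c(nnA, nnB)
  fin <- is.finite(nn)
  if (!any(fin)) stop("no finite distances", call. = FALSE)
  structure(mean(nn[fin]), dropped = sum(!fin))
}

#' Mean shortest distance within or between vertex sets
#'
#' `mode = "within"`: mean over members of `A` of the shortest-path
#' distance to the nearest *other* member of `A`. `mode = "between"`: mean
#' over all members of `A` and of `B` of the distance to the nearest member
#' of the opposite set; vertices shared by both sets contribute distance 0.
#' Unreachable terms are dropped; their count is attached as attribute
#' `"dropped"`.
#'
#' @param net An `igraph` network.
#' @param A,B Character vectors of vertex IDs (B ignored for `within`).
#' @param mode `"within"` or `"between"`.
#' @return A single number with attribute `dropped`.
#' @export
mean_set_distance <- function(net, A, B = NULL, mode = c("within", "between")) {
  mode <- match.arg(mode)
  assert_graph(net)
  ids <- vertex_ids(net)
  idxA <- match(unique(A), ids)
  if (anyNA(idxA)) stop("A contains vertices not in the network", call. = FALSE)
  if (length(idxA) == 0L) stop("A is empty", call. = FALSE)
  if (mode == "within") {
    D <- igraph::distances(net, v = idxA, to = idxA)
    return(set_dist_within_direct(D))
  }
  idxB <- match(unique(B), ids)
  if (anyNA(idxB) || length(idxB) == 0L) {
    stop("B must be a non-empty subset of the vertices", call. = FALSE)
  }
  DA <- igraph::distances(net, v = idxA, to = idxB)
  nnA <- apply(DA, 1L, min)
  nnB <- apply(DA, 2L, min)
  nn <- c(nnA, nnB)
  fin <- is.finite(nn)
  if (!any(fin)) stop("no finite distances", call. = FALSE)
  structure(mean(nn[fin]), dropped = sum(!fin))
}

set_dist_within_direct <- function(D) {
  if (nrow(D) < 2L) stop("within-set distance needs at least 2 members",
                         call. = FALSE)
  diag(D) <- Inf
  nn <- apply(D, 1L, min)
  fin <- is.finite(nn)
  if (!any(fin)) stop("no finite distances", call. = FALSE)
  structure(mean(nn[fin]), dropped = sum(!fin))
}

#' Topological separation of two annotation sets
#'
#' The separation statistic `s_AB = d_AB - (d_AA + d_BB) / 2`, where
#' `d_AA`, `d_BB` are the within-set mean nearest-member distances and
#' `d_AB` the between-set mean nearest-opposite-member distance (shared
#' members at distance 0). Negative values mean the two sets overlap
#' topologically (e.g. comorbid disease modules); positive values mean they
#' occupy separated network neighbourhoods.
#'
#' @param net An `igraph` network.
#' @param A,B Character vectors of vertex IDs, each of size >= 2.
#' @return A one-row tibble: `d_AA`, `d_BB`, `d_AB`, `s_AB`, `n_A`, `n_B`,
#'   `unreachable`.
#' @export
separation <- function(net, A, B) {
  d_aa <- mean_set_distance(net, A, mode = "within")
  d_bb <- mean_set_distance(net, B, mode = "within")
  d_ab <- mean_set_distance(net, A, B, mode = "between")
  tibble::tibble(
    d_AA = as.numeric(d_aa), d_BB = as.numeric(d_bb), d_AB = as.numeric(d_ab),
    s_AB = as.numeric(d_ab) - (as.numeric(d_aa) + as.numeric(d_bb)) / 2,
    n_A = length(unique(A)), n_B = length(unique(B)),
    unreachable = attr(d_aa, "dropped") + attr(d_bb, "dropped") +
      attr(d_ab, "dropped")
  )
}

# Separation statistic for index sets on a precomputed distance matrix;
# returns NA if any component is degenerate.
s_ab_from_D <- function(D, idxA, idxB) {
  daa <- tryCatch(as.numeric(set_dist_within(D, idxA)), error = function(e) NA_real_)
  dbb <- tryCatch(as.numeric(set_dist_within(D, idxB)), error = function(e) NA_real_)
  dab <- tryCatch(as.numeric(set_dist_between(D, idxA, idxB)),
                  error = function(e) NA_real_)
  dab - (daa + dbb) / 2
}

resolve_pairs <- function(term_sets, pairs) {
  term_names <- names(term_sets)
  if (is.character(pairs) && length(pairs) == 1L && pairs == "all") {
    if (length(term_names) < 2L) stop("need at least two terms", call. = FALSE)
    cmb <- utils::combn(sort(term_names), 2L)
    return(data.frame(term_a = cmb[1L, ], term_b = cmb[2L, ],
                      stringsAsFactors = FALSE))
  }
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("term_a", "term_b")
  miss <- setdiff(unique(c(pairs$term_a, pairs$term_b)), term_names)
  if (length(miss) > 0L) {
    stop(sprintf("term(s) absent from the annotation attribute: %s",
                 paste(utils::head(miss, 5L), collapse = ", ")), call. = FALSE)
  }
  pairs[, 1:2]
}

#' Quick annotation-pair overlap check against one permutation
#'
#' For each pair of annotation terms, computes the observed separation
#' `s_AB` and the same statistic on a single randomly annotated copy of the
#' network: every term keeps its vertex count but is re-assigned to
#' uniformly drawn vertices, independently across terms. Useful as a fast
#' sanity check before committing to a full permutation test.
#'
#' @param net An annotated `igraph` network.
#' @param attr_name Vertex attribute holding semicolon-separated terms.
#' @param pairs `"all"` or a two-column data frame of term pairs.
#' @param seed Optional integer seed.
#' @return A tibble `term_a`, `term_b`, `s_obs`, `s_perm`.
#' @export
calc_annotation_pairs <- function(net, attr_name, pairs = "all", seed = NULL) {
  assert_graph(net)
  term_sets <- attr_term_sets(net, attr_name)
  small <- names(term_sets)[lengths(term_sets) < 2L]
  term_sets <- term_sets[lengths(term_sets) >= 2L]
  pairs <- resolve_pairs(term_sets, pairs)
  ids <- vertex_ids(net)
  D <- igraph::distances(net)
  idx_sets <- lapply(term_sets, function(v) match(v, ids))
  # one permuted replicate: every term keeps its vertex count but is
  # re-assigned to uniformly drawn vertices, independently across terms
  idx_perm <- local_seed(seed, {
    lapply(idx_sets, function(ix) sample.int(length(ids), length(ix)))
  })
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$term_a[i]; b <- pairs$term_b[i]
    tibble::tibble(
      term_a = a, term_b = b,
      s_obs = s_ab_from_D(D, idx_sets[[a]], idx_sets[[b]]),
      s_perm = s_ab_from_D(D, idx_perm[[a]], idx_perm[[b]])
    )
  })
  dplyr::bind_rows(rows)
}

#' Permutation test of annotation-pair overlap
#'
#' Builds a null distribution for each pair's separation statistic by
#' randomly re-annotating the network `n_perm` times: every term keeps its
#' vertex count but its members are re-drawn uniformly, independently
#' across terms (the network itself is untouched). The empirical
#' p-value addresses the overlap direction:
#' `p = (1 + #\{s_null <= s_obs\}) / (n_perm + 1)`, so small p means the
#' observed sets overlap more than annotation placement by chance allows.
#' Bonferroni adjustment is over the tested pairs; q-values use the
#' Benjamini-Hochberg estimate.
#'
#' @param net An annotated `igraph` network.
#' @param attr_name Vertex attribute holding semicolon-separated terms.
#' @param pairs `"all"` or a two-column data frame of term pairs.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional integer seed.
#' @return A tibble `term_a`, `term_b`, `observed`, `null_mean`, `null_sd`,
#'   `z`, `p`, `p_bonferroni`, `q`, `n_perm`.
#' @export
run_permutation_test <- function(net, attr_name, pairs = "all",
                                 n_perm = 1000L, seed = NULL) {
  assert_graph(net)
  stopifnot(n_perm >= 100L)
  term_sets <- attr_term_sets(net, attr_name)
  term_sets <- term_sets[lengths(term_sets) >= 2L]
  pairs <- resolve_pairs(term_sets, pairs)
  ids <- vertex_ids(net)
  n <- length(ids)
  D <- igraph::distances(net)
  idx_sets <- lapply(term_sets, function(v) match(v, ids))
  obs <- vapply(seq_len(nrow(pairs)), function(i) {
    s_ab_from_D(D, idx_sets[[pairs$term_a[i]]], idx_sets[[pairs$term_b[i]]])
  }, numeric(1L))
  null_mat <- matrix(NA_real_, nrow = n_perm, ncol = nrow(pairs))
  for (r in seq_len(n_perm)) {
    idx_perm <- local_seed(derive_seed(seed, r), {
      lapply(idx_sets, function(ix) sample.int(n, length(ix)))
    })
    null_mat[r, ] <- vapply(seq_len(nrow(pairs)), function(i) {
      s_ab_from_D(D, idx_perm[[pairs$term_a[i]]], idx_perm[[pairs$term_b[i]]])
    }, numeric(1L))
  }
  p <- vapply(seq_len(nrow(pairs)), function(i) {
    (1 + sum(null_mat[, i] <= obs[i], na.rm = TRUE)) / (n_perm + 1)
  }, numeric(1L))
  nm <- colMeans(null_mat, na.rm = TRUE)
  nsd <- apply(null_mat, 2L, stats::sd, na.rm = TRUE)
  tibble::tibble(
    term_a = pairs$term_a, term_b = pairs$term_b,
    observed = obs, null_mean = nm, null_sd = nsd,
    z = (obs - nm) / nsd,
    p = p,
    p_bonferroni = pmin(1, p * nrow(pairs)),
    q = stats::p.adjust(p, method = "BH"),
    n_perm = as.integer(n_perm)
  )
}

#' Over-representation analysis of annotation terms in vertex groups
#'
#' For every (group, term) combination with a non-empty overlap, tests
#' whether the term's vertices are over-represented in the group by the
#' one-sided hypergeometric tail: with universe size `N`, term size `K`,
#' group size `n` and overlap `k`,
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Benjamini-Hochberg
#' adjustment is applied across all rows. Vertices outside the universe are
#' dropped with a message.
#'
#' @param groups Named list of vertex-ID vectors (e.g. communities), or a
#'   two-column data frame (group, vertex_id).
#' @param ann Annotation table (`term_id`, `term_name`, `vertex_id`).
#' @param universe Character vector of vertex IDs forming the background.
#' @return A tibble `group`, `term_id`, `term_name`, `k`, `n`, `K`, `N`,
#'   `p`, `p_adj`, `vertices` (semicolon-joined, sorted overlap members).
#' @export
ora <- function(groups, ann, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (is.data.frame(groups)) {
    groups <- split(as.character(groups[[2L]]), as.character(groups[[1L]]))
  }
  ann <- as.data.frame(ann)
  names(ann)[1:3] <- c("term_id", "term_name", "vertex_id")
  ann$vertex_id <- as.character(ann$vertex_id)
  n_out <- sum(!ann$vertex_id %in% universe)
  if (n_out > 0L) {
    message(sprintf("ora: dropped %d annotation row(s) outside the universe", n_out))
    ann <- ann[ann$vertex_id %in% universe, , drop = FALSE]
  }
  groups <- lapply(groups, function(g) intersect(unique(as.character(g)), universe))
  term_sets <- split(ann$vertex_id, ann$term_id)
  term_sets <- lapply(term_sets, unique)
  term_names <- vapply(split(as.character(ann$term_name), ann$term_id),
                       function(x) x[1L], character(1L))
  N <- length(universe)
  rows <- list()
  for (gname in names(groups)) {
    g <- groups[[gname]]
    for (tname in names(term_sets)) {
      ts <- term_sets[[tname]]
      hit <- intersect(g, ts)
      k <- length(hit)
      if (k == 0L) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = gname, term_id = tname, term_name = unname(term_names[tname]),
        k = k, n = length(g), K = length(ts), N = N,
        p = stats::phyper(k - 1L, length(ts), N - length(ts), length(g),
                          lower.tail = FALSE),
        vertices = paste(sort(hit), collapse = ";")
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(group = character(), term_id = character(),
                          term_name = character(), k = integer(), n = integer(),
                          K = integer(), N = integer(), p = numeric(),
                          p_adj = numeric(), vertices = character()))
  }
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  dplyr::relocate(out, "p_adj", .after = "p")
}

#' Intra-class edge enrichment
#'
#' Counts the edges whose two endpoints carry the same class label (e.g.
#' genes annotated to the same disorder class) and compares the count to a
#' null obtained by permuting the class labels over the vertices,
#' preserving class sizes. The empirical p-value is one-sided for
#' enrichment, with the +1 correction.
#'
#' @param net An `igraph` network.
#' @param class_attr Name of a single-valued vertex attribute.
#' @param n_perm Number of label permutations.
#' @param seed Optional integer seed.
#' @return A one-row tibble: `observed`, `null_mean`, `null_sd`, `p`,
#'   `n_perm`.
#' @export
intra_class_edges <- function(net, class_attr, n_perm = 1000L, seed = NULL) {
  assert_graph(net)
  cls <- igraph::vertex_attr(net, class_attr)
  if (is.null(cls)) stop(sprintf("vertex attribute '%s' not found", class_attr),
                         call. = FALSE)
  cls <- as.character(cls)
  el <- igraph::as_edgelist(net, names = FALSE)
  observed <- sum(cls[el[, 1L]] == cls[el[, 2L]])
  if (length(unique(cls)) == 1L) {
    return(tibble::tibble(observed = observed, null_mean = observed,
                          null_sd = 0, p = 1, n_perm = as.integer(n_perm)))
  }
  null <- vapply(seq_len(n_perm), function(r) {
    pc <- local_seed(derive_seed(seed, r), sample(cls))
    sum(pc[el[, 1L]] == pc[el[, 2L]])
  }, numeric(1L))
  tibble::tibble(
    observed = observed,
    null_mean = mean(null),
    null_sd = stats::sd(null),
    p = (1 + sum(null >= observed)) / (n_perm + 1),
    n_perm = as.integer(n_perm)
  )
}
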