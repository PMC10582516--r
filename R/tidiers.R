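# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a clustering into a vertex-level tibble
#'
#' @param x A `network_clustering`.
#' @param ... Unused.
#' @return A tibble `vertex_id`, `community`.
#' @export
tidy.network_clustering <- function(x, ...) {
  tibble::tibble(vertex_id = names(x$membership),
                 community = unname(x$membership))
}

#' One-row clustering summary
#'
#' @param x A `network_clustering`.
#' @param ... Unused.
#' @return A tibble `algorithm`, `n_communities`, `modularity`.
#' @export
glance.network_clustering <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm,
                 n_communities = x$n_communities,
                 modularity = x$modularity)
}

#' Tidy a power-law fit
#'
#' @param x A `powerlaw_fit`.
#' @param ... Unused.
#' @return A tibble `term`, `estimate`.
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "xmin"),
                 estimate = c(x$alpha, as.numeric(x$xmin)))
}

#' One-row power-law fit summary
#'
#' @param x A `powerlaw_fit`.
#' @param ... Unused.
#' @return A tibble `alpha`, `xmin`, `ks_stat`, `n_tail`, `p_boot`.
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, xmin = x$xmin, ks_stat = x$ks_stat,
                 n_tail = x$n_tail, p_boot = x$p_boot)
}

#' Tidy a consensus matrix into vertex pairs
#'
#' @param x A `consensus_matrix`.
#' @param ... Unused.
#' @return A tibble `vertex_a`, `vertex_b`, `consensus` over unordered
#'   pairs.
#' @export
tidy.consensus_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$M), arr.ind = TRUE)
  tibble::tibble(
    vertex_a = x$vertices[ut[, 1L]],
    vertex_b = x$vertices[ut[, 2L]],
    consensus = x$M[ut]
  )
}

#' One-row consensus-matrix summary
#'
#' @param x A `consensus_matrix`.
#' @param ... Unused.
#' @return A tibble `algorithm`, `n_vertices`, `reps`, `sample_fraction`,
#'   `mean_consensus`.
#' @export
glance.consensus_matrix <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm,
                 n_vertices = length(x$vertices),
                 reps = x$reps,
                 sample_fraction = x$sample_fraction,
                 mean_consensus = mean(x$M[upper.tri(x$M)]))
}
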