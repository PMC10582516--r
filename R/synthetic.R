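# Synthetic study-condition generators. Every generator is bit-reproducible
# given its seed and emits outputs that satisfy the preconditions of the
# modules consuming them.

#' Planted-partition community graph
#'
#' Independent edge coin-flips: probability `p_in` inside a block, `p_out`
#' between blocks. The planted block membership (the ground truth for
#' community-recovery tests) is stored alongside the graph.
#'
#' @param n_blocks Number of blocks.
#' @param block_size Vertices per block.
#' @param p_in,p_out Within-/between-block edge probabilities,
#'   `0 <= p_out < p_in <= 1`.
#' @param seed Optional integer seed.
#' @return An object of class `planted_graph`: list with `graph` (igraph,
#'   vertex attribute `block`), `true_membership` (named integer), `params`.
#' @export
planted_partition <- function(n_blocks, block_size, p_in, p_out, seed = NULL) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1", call. = FALSE)
  }
  n <- n_blocks * block_size
  blocks <- rep(seq_len(n_blocks), each = block_size)
  g <- local_seed(seed, {
    pref <- matrix(p_out, n_blocks, n_blocks)
    diag(pref) <- p_in
    igraph::sample_sbm(n, pref.matrix = pref,
                       block.sizes = rep(block_size, n_blocks))
  })
  ids <- sprintf("v%03d", seq_len(n))
  igraph::V(g)$name <- ids
  g <- igraph::set_vertex_attr(g, "block", value = blocks)
  structure(
    list(graph = g,
         true_membership = stats::setNames(blocks, ids),
         params = list(n_blocks = n_blocks, block_size = block_size,
                       p_in = p_in, p_out = p_out, seed = seed)),
    class = "planted_graph"
  )
}

#' @export
print.planted_graph <- function(x, ...) {
  p <- x$params
  cat(sprintf("Planted partition: %d blocks x %d vertices, p_in = %g, p_out = %g\n",
              p$n_blocks, p$block_size, p$p_in, p$p_out))
  invisible(x)
}

#' Annotation table for a planted-partition graph
#'
#' Draws term vertex sets so that the expected sign of the separation
#' statistic and the expected ORA enrichment are known by construction:
#' `"same_block"` confines term `i` to block `((i - 1) mod B) + 1` (terms
#' sharing a block overlap topologically; ORA should flag the block's
#' community), `"cross_block"` splits each term evenly over two consecutive
#' blocks, and `"random"` samples uniformly over all vertices (a calibrated
#' null for the permutation tests).
#'
#' @param pg A [planted_partition()] object.
#' @param n_terms Number of annotation terms.
#' @param term_size Vertices per term (`<= block_size` for the block modes).
#' @param overlap_mode `"same_block"`, `"cross_block"` or `"random"`.
#' @param seed Optional integer seed.
#' @return A tibble (`term_id`, `term_name`, `vertex_id`).
#' @export
annotated_planted_graph <- function(pg, n_terms, term_size,
                                    overlap_mode = c("same_block", "cross_block",
                                                     "random"),
                                    seed = NULL) {
  overlap_mode <- match.arg(overlap_mode)
  stopifnot(inherits(pg, "planted_graph"), n_terms >= 1L, term_size >= 1L)
  bs <- pg$params$block_size
  nb <- pg$params$n_blocks
  if (overlap_mode != "random" && term_size > bs) {
    stop("term_size must not exceed block_size for block modes", call. = FALSE)
  }
  ids <- names(pg$true_membership)
  blocks <- pg$true_membership
  local_seed(seed, {
    rows <- lapply(seq_len(n_terms), function(i) {
      vs <- switch(overlap_mode,
        same_block = {
          b <- ((i - 1L) %% nb) + 1L
          sample(ids[blocks == b], term_size)
        },
        cross_block = {
          b1 <- ((i - 1L) %% nb) + 1L
          b2 <- (b1 %% nb) + 1L
          n1 <- ceiling(term_size / 2)
          c(sample(ids[blocks == b1], n1),
            sample(ids[blocks == b2], term_size - n1))
        },
        random = sample(ids, term_size)
      )
      tibble::tibble(term_id = sprintf("T%03d", i),
                     term_name = sprintf("term %03d", i),
                     vertex_id = vs)
    })
    dplyr::bind_rows(rows)
  })
}

#' Toy bipartite disease-gene network
#'
#' Each of `n_dis` disease vertices is linked to `edges_per_disease`
#' distinct genes sampled uniformly from `n_genes` gene vertices. Exercises
#' the bipartite projection and rewiring pipeline at test scale.
#'
#' @param n_dis,n_genes Part sizes.
#' @param edges_per_disease Genes per disease (`<= n_genes`).
#' @param seed Optional integer seed.
#' @return A bipartite `igraph` (diseases left, genes right) as from
#'   [build_bipartite()].
#' @export
toy_diseasome <- function(n_dis, n_genes, edges_per_disease, seed = NULL) {
  stopifnot(n_dis >= 1L, n_genes >= 1L, edges_per_disease >= 1L)
  if (edges_per_disease > n_genes) {
    stop("edges_per_disease must not exceed n_genes", call. = FALSE)
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  dis <- sprintf("D%03d", seq_len(n_dis))
  edges <- local_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_dis), function(d) {
      tibble::tibble(left = dis[d], right = sample(genes, edges_per_disease))
    }))
  })
  build_bipartite(edges)
}
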