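#' Build an undirected network from an edge table
#'
#' Constructs a simple undirected graph from a two-column table of vertex
#' interactor pairs (e.g. a protein-protein interaction edge list). Vertex
#' identifiers are coerced to stripped strings, so numeric gene identifiers
#' (Entrez IDs) survive round trips through files unchanged.
#'
#' @param edge_table A data frame whose first two columns are the edge
#'   endpoints. Additional columns are ignored.
#' @param keep_lcc If `TRUE`, only the largest connected component is
#'   retained (ties broken by the component containing the lexicographically
#'   smallest vertex ID).
#' @param simplify If `TRUE` (default), self-loops and duplicate edges are
#'   removed.
#' @return An undirected `igraph` object with character vertex names.
#' @examples
#' edges <- data.frame(a = c("A", "B", "C", "D"), b = c("B", "C", "A", "E"))
#' net <- build_network(edges, keep_lcc = TRUE)
#' igraph::vcount(net) # 3
#' @export
build_network <- function(edge_table, keep_lcc = FALSE, simplify = TRUE) {
  edge_table <- as.data.frame(edge_table)
  if (nrow(edge_table) == 0L) stop("no edges", call. = FALSE)
  if (ncol(edge_table) < 2L) stop("edge table needs two endpoint columns", call. = FALSE)
  a <- trimws(as.character(edge_table[[1L]]))
  b <- trimws(as.character(edge_table[[2L]]))
  bad <- which(is.na(edge_table[[1L]]) | is.na(edge_table[[2L]]) | a == "" | b == "")
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge row(s): %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  net <- igraph::graph_from_data_frame(data.frame(a, b, stringsAsFactors = FALSE),
                                       directed = FALSE)
  if (simplify) net <- igraph::simplify(net, remove.multiple = TRUE, remove.loops = TRUE)
  if (keep_lcc) net <- largest_component(net)
  ensure_names(net)
}

#' Extract the largest connected component
#'
#' Returns the induced subgraph on the largest connected component. When
#' several components tie on size the one containing the lexicographically
#' smallest vertex ID is chosen, making the operation deterministic.
#' Idempotent: applying it twice equals applying it once.
#'
#' @param net An `igraph` network.
#' @return The induced subgraph on the largest component.
#' @export
largest_component <- function(net) {
  assert_graph(net)
  net <- ensure_names(net)
  comps <- igraph::components(net)
  sizes <- comps$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # pick the tied component holding the smallest vertex ID
    reps <- vapply(best, function(ci) {
      min(vertex_ids(net)[comps$membership == ci])
    }, character(1L))
    best <- best[order(reps)][1L]
  }
  igraph::induced_subgraph(net, which(comps$membership == best))
}

#' Read a network from a file
#'
#' Supports plain edge lists (whitespace- or comma-separated, optional
#' header), GML and GraphML. The vertex name attribute becomes the vertex ID.
#'
#' For edge lists the first two columns are the endpoints. A header line is
#' auto-detected: the first line is dropped only when both of its tokens are
#' non-numeric and appear nowhere else in the file as vertex IDs.
#'
#' @param path Path to the graph file.
#' @param format One of `"edgelist"`, `"gml"`, `"graphml"`.
#' @param simplify Remove loops/duplicate edges after reading (default TRUE).
#' @return An undirected `igraph` network.
#' @export
read_network <- function(path, format = c("edgelist", "gml", "graphml"),
                         simplify = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "edgelist") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    if (length(lines) == 0L) stop("no edges", call. = FALSE)
    toks <- lapply(lines, function(l) strsplit(trimws(l), "[,\t ]+")[[1L]])
    short <- which(vapply(toks, length, 1L) < 2L)
    if (length(short) > 0L) {
      stop(sprintf("parse failure at line %d: fewer than two columns", short[1L]),
           call. = FALSE)
    }
    ab <- t(vapply(toks, function(t) t[1:2], character(2L)))
    # header heuristic: both tokens non-numeric and never used as IDs below
    if (nrow(ab) > 1L) {
      h <- ab[1L, ]
      rest <- unique(c(ab[-1L, 1L], ab[-1L, 2L]))
      if (all(is.na(suppressWarnings(as.numeric(h)))) && !any(h %in% rest)) {
        ab <- ab[-1L, , drop = FALSE]
      }
    }
    net <- build_network(data.frame(a = ab[, 1L], b = ab[, 2L]), simplify = simplify)
    return(net)
  }
  net <- tryCatch(
    igraph::read_graph(path, format = format),
    error = function(e) stop(sprintf("failed to parse %s as %s: %s",
                                     path, format, conditionMessage(e)), call. = FALSE)
  )
  net <- igraph::as_undirected(net, mode = "collapse")
  if (is.null(igraph::V(net)$name)) {
    lab <- igraph::V(net)$label %||% igraph::V(net)$id
    igraph::V(net)$name <- if (is.null(lab)) {
      as.character(seq_len(igraph::vcount(net)))
    } else {
      as.character(lab)
    }
  }
  if (simplify) net <- igraph::simplify(net)
  ensure_names(net)
}

#' Write a network to a file
#'
#' Emits deterministic output: vertices sorted by ID and edges sorted
#' lexicographically, so repeated writes of the same graph are byte-identical.
#'
#' @param net An `igraph` network.
#' @param path Output path.
#' @param format One of `"edgelist"`, `"gml"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edgelist", "gml", "graphml")) {
  format <- match.arg(format)
  assert_graph(net)
  net <- ensure_names(net)
  perm <- order(vertex_ids(net))
  net <- igraph::permute(net, order(perm))
  if (format == "edgelist") {
    el <- igraph::as_edgelist(net, names = TRUE)
    swap <- el[, 1L] > el[, 2L]
    el[swap, ] <- el[swap, c(2L, 1L)]
    el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
    writeLines(c("id_a\tid_b", paste(el[, 1L], el[, 2L], sep = "\t")), path)
  } else {
    igraph::write_graph(net, path, format = format)
  }
  invisible(path)
}

#' Attach annotation terms to vertices
#'
#' Annotations come as a three-column table (`term_id`, `term_name`,
#' `vertex_id`). Each vertex gains a new attribute holding the
#' semicolon-joined, deduplicated, lexicographically sorted list of its
#' terms; annotated-nowhere vertices get the empty string. Rows referencing
#' vertices absent from the network are skipped with a reported count.
#'
#' @param net An `igraph` network.
#' @param ann Data frame with columns `term_id`, `term_name`, `vertex_id`
#'   (taken positionally if names differ).
#' @param attr_name Name of the vertex attribute to create.
#' @param id_field Which annotation column to store: `"term_id"` or
#'   `"term_name"`.
#' @return The annotated network.
#' @export
annotate_vertices <- function(net, ann, attr_name,
                              id_field = c("term_id", "term_name")) {
  assert_graph(net)
  id_field <- match.arg(id_field)
  if (!is.character(attr_name) || length(attr_name) != 1L || !nzchar(attr_name)) {
    stop("`attr_name` must be a non-empty string", call. = FALSE)
  }
  ann <- as.data.frame(ann)
  if (ncol(ann) < 3L) stop("annotation table needs 3 columns", call. = FALSE)
  names(ann)[1:3] <- c("term_id", "term_name", "vertex_id")
  ann$vertex_id <- trimws(as.character(ann$vertex_id))
  term <- trimws(as.character(ann[[id_field]]))
  keep <- !is.na(term) & nzchar(term) & nzchar(ann$vertex_id)
  ann <- ann[keep, , drop = FALSE]
  term <- term[keep]
  ids <- vertex_ids(net)
  known <- ann$vertex_id %in% ids
  n_skip <- sum(!known)
  if (n_skip > 0L) {
    message(sprintf("annotate_vertices: skipped %d row(s) referencing unknown vertices",
                    n_skip))
  }
  ann <- ann[known, , drop = FALSE]
  term <- term[known]
  joined <- vapply(split(term, factor(ann$vertex_id, levels = ids)), function(tt) {
    if (length(tt) == 0L) "" else paste(sort(unique(tt)), collapse = ";")
  }, character(1L))
  igraph::set_vertex_attr(net, attr_name, value = unname(joined[ids]))
}

#' Store per-vertex numeric columns as vertex attributes
#'
#' Each numeric column of `values` becomes a vertex attribute; vertices
#' missing from the table receive `NA`.
#'
#' @param net An `igraph` network.
#' @param values Data frame with a `vertex_id` column (or row names) and one
#'   or more numeric columns.
#' @param overwrite Allow replacing attributes that already exist.
#' @return The network with new attributes.
#' @export
apply_matrix_to_graph <- function(net, values, overwrite = FALSE) {
  assert_graph(net)
  values <- as.data.frame(values)
  if (nrow(values) == 0L || ncol(values) == 0L) return(net)
  if ("vertex_id" %in% names(values)) {
    key <- as.character(values$vertex_id)
    cols <- setdiff(names(values), "vertex_id")
  } else {
    key <- rownames(values)
    cols <- names(values)
  }
  ids <- vertex_ids(net)
  idx <- match(ids, key)
  existing <- igraph::vertex_attr_names(net)
  for (cn in cols) {
    if (cn %in% existing && !overwrite) {
      stop(sprintf("vertex attribute '%s' already exists (set overwrite = TRUE)", cn),
           call. = FALSE)
    }
    net <- igraph::set_vertex_attr(net, cn, value = values[[cn]][idx])
  }
  net
}

#' Build a bipartite network
#'
#' Edges join a "left" vertex (first column, e.g. a disease) to a "right"
#' vertex (second column, e.g. a gene). An identifier may not appear in both
#' parts.
#'
#' @param edge_table Data frame whose first two columns are (left_id,
#'   right_id) pairs.
#' @return An undirected bipartite `igraph` with vertex attributes `part`
#'   (`"left"`/`"right"`) and logical `type` (`TRUE` = right).
#' @export
build_bipartite <- function(edge_table) {
  edge_table <- as.data.frame(edge_table)
  if (nrow(edge_table) == 0L) stop("no edges", call. = FALSE)
  l <- trimws(as.character(edge_table[[1L]]))
  r <- trimws(as.character(edge_table[[2L]]))
  if (any(!nzchar(l)) || any(!nzchar(r)) || anyNA(l) || anyNA(r)) {
    stop("malformed bipartite edge rows (empty or missing IDs)", call. = FALSE)
  }
  both <- intersect(unique(l), unique(r))
  if (length(both) > 0L) {
    stop(sprintf("IDs present in both parts: %s",
                 paste(utils::head(both, 3L), collapse = ", ")), call. = FALSE)
  }
  net <- build_network(data.frame(a = l, b = r), simplify = TRUE)
  part <- ifelse(vertex_ids(net) %in% unique(r), "right", "left")
  net <- igraph::set_vertex_attr(net, "part", value = part)
  igraph::set_vertex_attr(net, "type", value = part == "right")
}

#' Project a bipartite network onto one part
#'
#' Two vertices of the chosen part are joined if and only if they share at
#' least one neighbour in the opposite part (e.g. two genes linked to the
#' same disease). The projection is simple and unweighted.
#'
#' @param bn A bipartite network from [build_bipartite()].
#' @param onto `"left"` or `"right"`.
#' @return An undirected `igraph` on the chosen part.
#' @export
project_bipartite <- function(bn, onto = c("left", "right")) {
  onto <- match.arg(onto)
  assert_graph(bn)
  part <- igraph::V(bn)$part
  if (is.null(part)) stop("`bn` is not a bipartite network (no 'part' attribute)",
                          call. = FALSE)
  if (!any(part == onto)) stop(sprintf("part '%s' is empty", onto), call. = FALSE)
  proj <- igraph::bipartite_projection(bn, types = igraph::V(bn)$type)
  out <- if (onto == "left") proj$proj1 else proj$proj2
  out <- igraph::delete_edge_attr(out, "weight")
  ensure_names(igraph::simplify(out))
}

#' Degree-preserving rewiring of a bipartite network
#'
#' Randomises connections while preserving the exact degree sequence of both
#' parts via attempted double-edge swaps; swaps that would create a duplicate
#' edge are rejected (the attempt is still counted).
#'
#' @param bn A bipartite network.
#' @param n_swaps Number of attempted swaps; default `10 * ecount(bn)`.
#' @param seed Optional integer seed.
#' @return A rewired bipartite network with identical degree sequences.
#' @export
rewire_bipartite <- function(bn, n_swaps = NULL, seed = NULL) {
  assert_graph(bn)
  part <- igraph::V(bn)$part
  if (is.null(part)) stop("`bn` is not a bipartite network", call. = FALSE)
  m <- igraph::ecount(bn)
  if (m < 2L) stop("need at least 2 edges to rewire", call. = FALSE)
  n_swaps <- n_swaps %||% (10L * m)
  stopifnot(n_swaps >= 0L)
  ids <- vertex_ids(bn)
  el <- igraph::as_edgelist(bn, names = FALSE)
  # orient every edge left -> right
  flip <- part[el[, 1L]] == "right"
  el[flip, ] <- el[flip, c(2L, 1L)]
  key <- function(l, r) paste0(l, "_", r)
  seen <- new.env(hash = TRUE, size = 2L * m)
  for (e in seq_len(m)) assign(key(el[e, 1L], el[e, 2L]), TRUE, envir = seen)
  local_seed(seed, {
    if (n_swaps > 0L) {
      pick <- matrix(sample.int(m, 2L * n_swaps, replace = TRUE), ncol = 2L)
      for (s in seq_len(n_swaps)) {
        e1 <- pick[s, 1L]; e2 <- pick[s, 2L]
        if (e1 == e2) next
        l1 <- el[e1, 1L]; r1 <- el[e1, 2L]
        l2 <- el[e2, 1L]; r2 <- el[e2, 2L]
        if (l1 == l2 || r1 == r2) next
        k1 <- key(l1, r2); k2 <- key(l2, r1)
        if (exists(k1, envir = seen, inherits = FALSE) ||
            exists(k2, envir = seen, inherits = FALSE)) next
        rm(list = c(key(l1, r1), key(l2, r2)), envir = seen)
        assign(k1, TRUE, envir = seen)
        assign(k2, TRUE, envir = seen)
        el[e1, 2L] <- r2
        el[e2, 2L] <- r1
      }
    }
  })
  out <- igraph::graph_from_edgelist(
    cbind(ids[el[, 1L]], ids[el[, 2L]]), directed = FALSE)
  # carry over isolated vertices and part labels
  miss <- setdiff(ids, vertex_ids(out))
  if (length(miss) > 0L) out <- igraph::add_vertices(out, length(miss), name = miss)
  pmap <- stats::setNames(part, ids)
  out <- igraph::set_vertex_attr(out, "part", value = unname(pmap[vertex_ids(out)]))
  igraph::set_vertex_attr(out, "type",
                          value = igraph::vertex_attr(out, "part") == "right")
}

#' Read an annotation table
#'
#' Reads a 3-column TSV with header `term_id  term_name  vertex_id`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the three annotation columns as character.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 3L) stop("annotation table needs 3 columns", call. = FALSE)
  names(df)[1:3] <- c("term_id", "term_name", "vertex_id")
  tibble::as_tibble(df[, 1:3])
}
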