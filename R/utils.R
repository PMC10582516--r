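# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# A NULL seed leaves the global RNG stream untouched.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a per-replicate seed from a master seed by a plain counter scheme,
# kept inside 32-bit integer range.
derive_seed <- function(seed, counter) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 7919L * as.integer(counter)) %% .Machine$integer.max
}

assert_graph <- function(net, arg = "net") {
  if (!igraph::is_igraph(net)) {
    stop(sprintf("`%s` must be an igraph object", arg), call. = FALSE)
  }
  if (igraph::vcount(net) == 0L) {
    stop(sprintf("`%s` is an empty graph", arg), call. = FALSE)
  }
  invisible(net)
}

vertex_ids <- function(net) {
  nm <- igraph::V(net)$name
  if (is.null(nm)) as.character(seq_len(igraph::vcount(net))) else as.character(nm)
}

# Ensure every vertex carries a non-empty string name.
ensure_names <- function(net) {
  nm <- igraph::V(net)$name
  if (is.null(nm)) {
    igraph::V(net)$name <- as.character(seq_len(igraph::vcount(net)))
  } else {
    igraph::V(net)$name <- trimws(as.character(nm))
  }
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a
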