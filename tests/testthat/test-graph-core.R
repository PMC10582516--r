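test_that("build_network simplifies, keeps the LCC and rejects bad input", {
  net <- build_network(data.frame(a = c("A", "B", "C", "D"),
                                  b = c("B", "C", "A", "E")),
                       keep_lcc = TRUE)
  expect_equal(igraph::vcount(net), 3L)
  expect_equal(igraph::ecount(net), 3L)
  expect_setequal(igraph::V(net)$name, c("A", "B", "C"))

  net2 <- build_network(data.frame(a = c("A", "A", "A"), b = c("A", "B", "B")))
  expect_equal(igraph::vcount(net2), 2L)
  expect_equal(igraph::ecount(net2), 1L)

  expect_error(build_network(data.frame(a = character(), b = character())),
               "no edges")
  expect_error(build_network(data.frame(a = c("A", NA), b = c("B", "C"))),
               "row.*2")
})

test_that("graph files round-trip identically in all three formats", {
  for (s in 1:4) {
    g <- build_network(igraph::as_data_frame(random_named_graph(9L, 0.35, s)))
    for (fmt in c("edgelist", "gml", "graphml")) {
      path <- tempfile(fileext = paste0(".", fmt))
      write_network(g, path, fmt)
      g2 <- read_network(path, fmt)
      expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
      el <- function(x) {
        e <- igraph::as_edgelist(x)
        swap <- e[, 1L] > e[, 2L]
        e[swap, ] <- e[swap, c(2L, 1L)]
        paste(e[, 1L], e[, 2L])
      }
      expect_setequal(el(g2), el(g))
      unlink(path)
    }
  }
})

test_that("edge-list reader handles headers, separators and comments", {
  path <- tempfile()
  writeLines(c("id_a\tid_b", "P1\tP2", "P2,P3", "# comment", "P3 P1"), path)
  net <- read_network(path, "edgelist")
  expect_setequal(igraph::V(net)$name, c("P1", "P2", "P3"))
  expect_equal(igraph::ecount(net), 3L)
  unlink(path)

  # a first line whose tokens recur as IDs is data, not a header
  path2 <- tempfile()
  writeLines(c("A\tB", "B\tC", "C\tA"), path2)
  expect_equal(igraph::ecount(read_network(path2, "edgelist")), 3L)
  unlink(path2)

  expect_error(read_network(tempfile(), "edgelist"), "not found")
})

test_that("largest_component is idempotent, connected and tie-broken by ID", {
  g <- build_network(rbind(clique_edges(c("x", "y", "z")),
                           data.frame(a = "d", b = "e")))
  lcc <- largest_component(g)
  expect_setequal(igraph::V(lcc)$name, c("x", "y", "z"))
  expect_true(igraph::is_connected(lcc))
  lcc2 <- largest_component(lcc)
  expect_setequal(igraph::V(lcc2)$name, igraph::V(lcc)$name)

  # tie between two 2-vertex components: the one holding "a" wins
  tie <- build_network(data.frame(a = c("m", "a"), b = c("n", "b")))
  expect_setequal(igraph::V(largest_component(tie))$name, c("a", "b"))
})

test_that("annotation joins are canonical and unknown vertices are skipped", {
  g <- build_network(data.frame(a = "v1", b = "v2"))
  ann <- data.frame(term_id = c("T2", "T1", "T1"),
                    term_name = c("bar", "foo", "foo"),
                    vertex_id = c("v1", "v1", "v1"))
  g2 <- annotate_vertices(g, ann, "terms")
  vals <- igraph::vertex_attr(g2, "terms")
  names(vals) <- igraph::V(g2)$name
  expect_equal(unname(vals["v1"]), "T1;T2")
  expect_equal(unname(vals["v2"]), "")

  ann_bad <- rbind(ann, data.frame(term_id = "T9", term_name = "q",
                                   vertex_id = "ghost"))
  expect_message(annotate_vertices(g, ann_bad, "terms"), "skipped 1")

  g3 <- annotate_vertices(g, ann, "named", id_field = "term_name")
  expect_equal(igraph::vertex_attr(g3, "named")[1L], "bar;foo")
})

test_that("apply_matrix_to_graph attaches columns and guards collisions", {
  g <- build_network(data.frame(a = c("v1", "v2"), b = c("v2", "v3")))
  g2 <- apply_matrix_to_graph(g, data.frame(vertex_id = "v1", deg = 3))
  vals <- igraph::vertex_attr(g2, "deg")
  expect_equal(vals[igraph::V(g2)$name == "v1"], 3)
  expect_true(is.na(vals[igraph::V(g2)$name == "v2"]))

  expect_identical(apply_matrix_to_graph(g, data.frame()), g)
  expect_error(apply_matrix_to_graph(g2, data.frame(vertex_id = "v1", deg = 9)),
               "already exists")
  g3 <- apply_matrix_to_graph(g2, data.frame(vertex_id = "v1", deg = 9),
                              overwrite = TRUE)
  expect_equal(igraph::vertex_attr(g3, "deg")[igraph::V(g3)$name == "v1"], 9)

  cm <- calc_centrality(g)
  g4 <- apply_matrix_to_graph(g, cm)
  expect_true(all(c("DEG", "BET", "CC", "SL", "mnSP", "PR", "sdSP") %in%
                    igraph::vertex_attr_names(g4)))
})

test_that("bipartite projection matches the shared-neighbour definition", {
  bn <- build_bipartite(data.frame(l = c("D1", "D1", "D2", "D2"),
                                   r = c("g1", "g2", "g2", "g3")))
  genes <- project_bipartite(bn, "right")
  e <- igraph::as_edgelist(genes)
  expect_setequal(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])),
                  c("g1 g2", "g2 g3"))
  dis <- project_bipartite(bn, "left")
  expect_equal(igraph::ecount(dis), 1L)

  # brute force on random bipartite graphs <= 12 vertices
  for (s in 1:5) {
    bnr <- toy_diseasome(4L, 8L, 3L, seed = s)
    pr <- project_bipartite(bnr, "right")
    part <- igraph::V(bnr)$part
    genes_ids <- igraph::V(bnr)$name[part == "right"]
    adj <- igraph::as_adj_list(bnr, mode = "all")
    names(adj) <- igraph::V(bnr)$name
    expected <- character()
    for (i in seq_along(genes_ids)) {
      for (j in seq_len(i - 1L)) {
        shared <- intersect(igraph::V(bnr)$name[as.integer(adj[[genes_ids[i]]])],
                            igraph::V(bnr)$name[as.integer(adj[[genes_ids[j]]])])
        if (length(shared) > 0L) {
          expected <- c(expected, paste(sort(c(genes_ids[i], genes_ids[j])),
                                        collapse = " "))
        }
      }
    }
    e <- igraph::as_edgelist(pr)
    got <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    expect_setequal(got, expected)
  }

  expect_error(build_bipartite(data.frame(l = "A", r = "A")), "both parts")
})

test_that("bipartite rewiring preserves both degree sequences exactly", {
  bn <- toy_diseasome(8L, 20L, 4L, seed = 3)
  canon <- function(g) {
    e <- igraph::as_edgelist(g)
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  }
  same <- rewire_bipartite(bn, n_swaps = 0L)
  expect_setequal(canon(same), canon(bn))
  for (s in 1:5) {
    rw <- rewire_bipartite(bn, seed = s)
    d0 <- igraph::degree(bn)
    d1 <- igraph::degree(rw)[names(d0)]
    expect_equal(unname(d1), unname(d0))
    expect_true(all(igraph::count_multiple(rw) == 1L))
  }
  tiny <- build_bipartite(data.frame(l = "D1", r = "g1"))
  expect_error(rewire_bipartite(tiny), "2 edges")
})
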