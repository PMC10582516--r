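test_that("mean set distances follow the nearest-member definition", {
  p5 <- build_network(path_edges(paste0("v", 1:5)))
  d <- mean_set_distance(p5, c("v1", "v5"), mode = "within")
  expect_equal(as.numeric(d), 4)
  expect_equal(as.numeric(mean_set_distance(p5, c("v1", "v3"), c("v1", "v3"),
                                            mode = "between")), 0)
  expect_error(mean_set_distance(p5, "v1", mode = "within"), "at least 2")

  disc <- build_network(data.frame(a = c("a", "c"), b = c("b", "d")))
  expect_error(mean_set_distance(disc, c("a", "b"), c("c", "d"),
                                 mode = "between"), "no finite distances")
})

test_that("separation statistic matches the brute-force evaluation", {
  # A = B gives s_AB = -d_AA <= 0
  p5 <- build_network(path_edges(paste0("v", 1:5)))
  res <- separation(p5, c("v1", "v2"), c("v1", "v2"))
  expect_equal(res$s_AB, -res$d_AA)
  expect_lte(res$s_AB, 0)

  for (s in 1:6) {
    g <- largest_component(random_named_graph(sample(8:20, 1L), 0.25, s + 600L))
    ids <- igraph::V(g)$name
    sets <- bionetkit:::local_seed(s, {
      list(A = sample(ids, min(4L, length(ids) - 2L)),
           B = sample(ids, min(5L, length(ids) - 2L)))
    })
    got <- separation(g, sets$A, sets$B)
    expect_equal(got$s_AB, brute_separation(g, sets$A, sets$B),
                 tolerance = 1e-12)
  }
})

test_that("planted annotation sets separate or overlap as constructed", {
  same_sign <- 0L
  diff_sign <- 0L
  for (s in 1:20) {
    pg <- planted_partition(2L, 12L, 0.8, 0.03, seed = s)
    ids <- names(pg$true_membership)
    pick <- bionetkit:::local_seed(s + 50L, {
      list(a1 = sample(ids[pg$true_membership == 1L], 5L),
           a2 = sample(ids[pg$true_membership == 1L], 5L),
           b = sample(ids[pg$true_membership == 2L], 5L))
    })
    if (separation(pg$graph, pick$a1, pick$b)$s_AB > 0) diff_sign <- diff_sign + 1L
    if (separation(pg$graph, pick$a1, pick$a2)$s_AB < 0) same_sign <- same_sign + 1L
  }
  expect_gte(diff_sign, 19L)
  expect_gte(same_sign, 19L)
})

test_that("quick annotation-pair check preserves term sizes and is seeded", {
  pg <- planted_partition(2L, 12L, 0.8, 0.03, seed = 4)
  ann <- annotated_planted_graph(pg, 4L, 6L, "same_block", seed = 5)
  net <- annotate_vertices(pg$graph, ann, "terms")

  tab <- calc_annotation_pairs(net, "terms", seed = 6)
  expect_identical(tab, calc_annotation_pairs(net, "terms", seed = 6))
  expect_equal(nrow(tab), choose(4L, 2L))
  expect_error(calc_annotation_pairs(net, "terms",
                                     pairs = data.frame(a = "T001", b = "T999")),
               "T999")

  # a pair sharing most members overlaps more than its permuted replicate
  ids <- names(pg$true_membership)
  core <- ids[1:7]
  ann2 <- tibble::tibble(term_id = rep(c("TA", "TB"), each = 6L),
                         term_name = rep(c("a", "b"), each = 6L),
                         vertex_id = c(core[1:6], core[2:7]))
  net2 <- annotate_vertices(pg$graph, ann2, "shared")
  tab2 <- calc_annotation_pairs(net2, "shared", seed = 8)
  expect_lt(tab2$s_obs, tab2$s_perm)
})

test_that("permutation p-values are honest and the planted pair ranks first", {
  firsts <- 0L
  for (s in 1:5) {
    pg <- planted_partition(2L, 12L, 0.85, 0.04, seed = s + 70L)
    ann <- annotated_planted_graph(pg, 4L, 6L, "random", seed = s + 80L)
    # replace the first two random terms with a pair sharing 5 of 6 members
    ids <- names(pg$true_membership)
    blk <- bionetkit:::local_seed(s, sample(ids[pg$true_membership == 1L], 7L))
    ann$vertex_id[ann$term_id == "T001"] <- blk[1:6]
    ann$vertex_id[ann$term_id == "T002"] <- blk[2:7]
    net <- annotate_vertices(pg$graph, ann, "terms")
    res <- run_permutation_test(net, "terms", n_perm = 100L, seed = s + 90L)
    expect_true(all(res$p > 0 & res$p <= 1))
    expect_equal(res$p_bonferroni, pmin(1, res$p * nrow(res)))
    expect_false(is.unsorted(res$q[order(res$p)]))
    top <- res[order(res$q, res$p), ]
    if (top$term_a[1L] == "T001" && top$term_b[1L] == "T002") {
      firsts <- firsts + 1L
    }
  }
  expect_equal(firsts, 5L)
})

test_that("ORA reproduces exact combinatorial p-values", {
  u <- paste0("v", 1:10)
  ann <- data.frame(term_id = "T1", term_name = "t", vertex_id = u[1:5])
  res <- ora(list(grp = u[1:4]), ann, u)
  expect_equal(res$p, 5 / 210) # C(5,4)C(5,0)/C(10,4)
  expect_equal(res$k, 4L)
  expect_equal(res$vertices, "v1;v2;v3;v4")

  # zero-overlap rows are omitted
  ann2 <- rbind(ann, data.frame(term_id = "T2", term_name = "u",
                                vertex_id = u[9:10]))
  res2 <- ora(list(grp = u[1:4]), ann2, u)
  expect_equal(res2$term_id, "T1")

  # a term equal to the group gives that group's smallest p
  ann3 <- rbind(ann, data.frame(term_id = "T3", term_name = "w",
                                vertex_id = u[1:4]))
  res3 <- ora(list(grp = u[1:4]), ann3, u)
  expect_equal(res3$term_id[which.min(res3$p)], "T3")

  expect_message(ora(list(g = u[1:2]),
                     data.frame(term_id = "T1", term_name = "t",
                                vertex_id = c(u[1:2], "zz")), u),
                 "outside the universe")
  expect_error(ora(list(g = "v1"), ann, character()), "empty universe")
})

test_that("ORA p-values match the exhaustive oracle across configurations", {
  for (N in c(6L, 13L, 30L)) {
    u <- paste0("v", seq_len(N))
    groups <- lapply(seq_len(N - 1L), function(n) u[seq_len(n)])
    names(groups) <- paste0("g", seq_len(N - 1L))
    terms <- list()
    for (K in seq_len(N)) {
      for (off in seq.int(0L, N - K, by = max(1L, K %/% 2L))) {
        terms[[length(terms) + 1L]] <-
          data.frame(term_id = sprintf("K%d_o%d", K, off), term_name = "t",
                     vertex_id = u[(off + 1L):(off + K)])
      }
    }
    res <- ora(groups, do.call(rbind, terms), u)
    oracle <- mapply(brute_hyper_p, res$k, res$K, res$n,
                     MoreArgs = list(N = N))
    expect_equal(res$p, oracle, tolerance = 1e-12)
    expect_true(all(res$k <= pmin(res$n, res$K)))
  }
})

test_that("intra-class edge counts are calibrated against the analytic null", {
  pg <- planted_partition(3L, 8L, 0.7, 0.05, seed = 8)
  g <- igraph::set_vertex_attr(pg$graph, "cls",
                               value = as.character(pg$true_membership))
  res <- intra_class_edges(g, "cls", n_perm = 300L, seed = 9)
  expect_lte(res$p, 0.01)

  # random labels: null mean agrees with sum_c n_c (n_c - 1) / (n (n - 1)) * |E|
  gr <- largest_component(random_named_graph(30L, 0.15, 10L))
  n <- igraph::vcount(gr)
  labs <- bionetkit:::local_seed(11, sample(rep(c("x", "y", "z"), length.out = n)))
  gr <- igraph::set_vertex_attr(gr, "cls", value = labs)
  res2 <- intra_class_edges(gr, "cls", n_perm = 400L, seed = 12)
  sizes <- table(labs)
  expected <- sum(sizes * (sizes - 1)) / (n * (n - 1)) * igraph::ecount(gr)
  expect_lt(abs(res2$null_mean - expected), 3 * res2$null_sd)

  # degenerate single class
  g1 <- igraph::set_vertex_attr(gr, "one", value = "same")
  res3 <- intra_class_edges(g1, "one", n_perm = 100L)
  expect_equal(res3$observed, igraph::ecount(gr))
  expect_equal(res3$p, 1)
})
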