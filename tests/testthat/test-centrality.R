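tight <- centrality_params(pagerank_epsilon = 1e-12,
                           eigenvector_iterations = 5000)

test_that("degree counts incident edges", {
  k5 <- complete_graph(5)
  expect_true(all(degree_centrality(k5) == 4))
  s5 <- star_graph(5)
  deg <- degree_centrality(s5)
  expect_equal(unname(deg["hub"]), 5L)
  expect_true(all(deg[paste0("leaf", 1:5)] == 1L))
  # handshake identity on random graphs
  set.seed(8)
  for (i in 1:20) {
    g <- random_graph(sample(3:12, 1))
    expect_equal(sum(degree_centrality(g)), 2L * nrow(g$edges))
  }
})

test_that("betweenness matches closed forms", {
  bc <- betweenness_centrality(path_graph(5))
  expect_equal(unname(bc), c(0, 3 / 6, 4 / 6, 3 / 6, 0))
  s <- star_graph(6)
  bcs <- betweenness_centrality(s)
  expect_equal(unname(bcs["hub"]), 1)
  expect_true(all(bcs[-1] == 0))
  expect_true(all(betweenness_centrality(complete_graph(5)) == 0))
  raw <- betweenness_centrality(path_graph(5),
                                centrality_params(betweenness_normalized = FALSE))
  expect_equal(unname(raw["c"]), 4)
})

test_that("eigenvector centrality solves the eigen-equation on stars and cycles", {
  s4 <- star_graph(4)
  ev <- eigenvector_centrality(s4, tight)
  expect_equal(unname(ev["hub"]), 1)
  expect_equal(unname(ev[paste0("leaf", 1:4)]), rep(1 / sqrt(4), 4),
               tolerance = 1e-9)
  c6 <- cycle_graph(6)
  expect_equal(unname(eigenvector_centrality(c6, tight)), rep(1, 6))
  expect_error(eigenvector_centrality(
    graph_from_edges("a", character(0), character(0))), "edgeless")
})

test_that("pagerank matches exact stationary solutions", {
  two <- graph_from_edges(c("a", "b"), "a", "b")
  expect_equal(unname(pagerank(two, tight)), c(0.5, 0.5))
  c4 <- cycle_graph(4)
  expect_equal(unname(pagerank(c4, tight)), rep(0.25, 4), tolerance = 1e-9)
  s3 <- star_graph(3)
  pr <- pagerank(s3, tight)
  expect_equal(unname(pr["hub"]), 0.4797297, tolerance = 1e-6)
  expect_equal(unname(pr["leaf1"]), 0.1734234, tolerance = 1e-6)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
})

test_that("isolated nodes are dangling but keep positive pagerank", {
  g <- graph_from_edges(c("a", "b", "iso"), "a", "b")
  pr <- pagerank(g, tight)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  expect_gt(pr[["iso"]], 0)
  expect_equal(degree_centrality(g)[["iso"]], 0L)
  ev <- eigenvector_centrality(g, tight)
  expect_equal(ev[["iso"]], 0)
})

test_that("all four metrics agree with the exhaustive oracles on small graphs", {
  set.seed(99)
  n_checked <- 0
  for (i in 1:60) {
    g <- random_graph(sample(4:9, 1), p = runif(1, 0.25, 0.7))
    if (nrow(g$edges) == 0) next
    main <- list(
      degree = degree_centrality(g),
      betweenness = betweenness_centrality(g, tight),
      eigenvector = eigenvector_centrality(g, tight),
      pagerank = pagerank(g, tight)
    )
    ref <- oracle_suite(g, tight)
    for (m in names(main)) {
      expect_equal(as.numeric(main[[m]]), as.numeric(ref[[m]]),
                   tolerance = 1e-6,
                   label = sprintf("%s on graph %d", m, i))
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 50)
  # the smallest case: one edge
  g1 <- graph_from_edges(c("a", "b"), "a", "b")
  ref1 <- oracle_suite(g1, tight)
  expect_equal(as.numeric(pagerank(g1, tight)), as.numeric(ref1$pagerank),
               tolerance = 1e-9)
  expect_equal(as.numeric(eigenvector_centrality(g1, tight)),
               as.numeric(ref1$eigenvector), tolerance = 1e-9)
  expect_error(oracle_suite(complete_graph(10)), "at most 9")
})

test_that("weighted betweenness follows the 1/weight distance transform", {
  # triangle where the direct a-c edge is weak: the strong two-hop route
  # via b is shorter under d = 1/w
  g <- graph_from_edges(c("a", "b", "c"),
                        from = c("a", "b", "a"), to = c("b", "c", "c"),
                        weight = c(0.9, 0.9, 0.3))
  wpar <- centrality_params(betweenness_weighted = TRUE)
  bw <- betweenness_centrality(g, wpar)
  expect_gt(bw[["b"]], 0)
  ref <- oracle_suite(g, wpar)
  expect_equal(as.numeric(bw), as.numeric(ref$betweenness), tolerance = 1e-9)
})

test_that("relabeling nodes permutes centralities consistently", {
  set.seed(12)
  g <- random_graph(8, p = 0.5)
  perm <- sample(8)
  relab <- setNames(paste0("m", seq_len(8)), g$nodes$variable[perm])
  g2 <- graph_from_edges(unname(relab[g$nodes$variable[perm]]),
                         unname(relab[g$edges$from]),
                         unname(relab[g$edges$to]),
                         weight = g$edges$weight)
  for (fn in list(degree_centrality,
                  function(x) betweenness_centrality(x, tight),
                  function(x) pagerank(x, tight))) {
    a <- fn(g)
    b <- fn(g2)
    expect_equal(unname(b[relab[names(a)]]), unname(a), tolerance = 1e-9)
  }
})

test_that("centrality agrees with igraph on a moderate random graph", {
  skip_if_not_installed("igraph")
  set.seed(33)
  g <- random_graph(20, p = 0.25)
  ig <- igraph::graph_from_data_frame(g$edges[1:2], directed = FALSE,
                                      vertices = g$nodes$variable)
  expect_equal(unname(degree_centrality(g)[igraph::V(ig)$name]),
               unname(igraph::degree(ig)))
  mine_b <- betweenness_centrality(g, centrality_params(
    betweenness_normalized = FALSE))
  expect_equal(unname(mine_b[igraph::V(ig)$name]),
               unname(igraph::betweenness(ig)), tolerance = 1e-9)
  mine_pr <- pagerank(g, tight)
  ref_pr <- igraph::page_rank(ig, damping = 0.85)$vector
  expect_equal(unname(mine_pr[igraph::V(ig)$name]), unname(ref_pr),
               tolerance = 1e-6)
})

test_that("the tidy centrality table covers every node and metric", {
  g <- star_graph(4)
  tab <- centrality(g, tight)
  expect_equal(nrow(tab), 4 * 5)
  expect_setequal(unique(tab$metric),
                  c("degree", "betweenness", "eigenvector", "pagerank"))
  edgeless <- graph_from_edges(c("a", "b"), character(0), character(0))
  tab2 <- centrality(edgeless, tight)
  expect_true(all(is.na(tab2$value[tab2$metric == "eigenvector"])))
  expect_false(anyNA(tab2$value[tab2$metric != "eigenvector"]))
})
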