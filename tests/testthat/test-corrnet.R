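test_that("pearson_r_p matches hand computation and the stats oracle", {
  expect_equal(unlist(pearson_r_p(c(1, 2, 3), c(2, 4, 6))),
               c(r = 1, p = 0, n = 3))
  expect_equal(pearson_r_p(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  # dual route: compare r and p with cor.test on random draws
  set.seed(20)
  for (i in 1:10) {
    x <- rnorm(15)
    y <- rnorm(15)
    mine <- pearson_r_p(x, y)
    ref <- cor.test(x, y)
    expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("the significance gate at n = 15 sits at |r| ~ 0.514", {
  expect_equal(critical_r(15), 0.514, tolerance = 1e-3)
  # r = 0.514 -> t = 2.160 on 13 df, p ~ 0.050
  pair <- pair_with_correlation(15, 0.514)
  res <- pearson_r_p(pair$x, pair$y)
  expect_equal(res$p, 0.05, tolerance = 2e-3)
  t_stat <- res$r * sqrt(13 / (1 - res$r^2))
  expect_equal(t_stat, 2.160, tolerance = 1e-3)
})

test_that("degenerate pairs are flagged, not silently zero", {
  expect_warning(res <- pearson_r_p(rep(1, 5), rnorm(5)), "zero variance")
  expect_true(is.na(res$r))
  expect_true(is.na(pearson_r_p(c(1, 2), c(3, 4))$r))
})

test_that("correlation matrices are symmetric with isolated undefined pairs", {
  set.seed(4)
  tab <- tibble::tibble(subject_id = as.character(1:10),
                        a = rnorm(10), b = rnorm(10), c = rnorm(10))
  tab$d <- tab$a  # identical pair
  corr <- correlation_matrices(tab)
  expect_equal(corr$R["a", "d"], 1)
  expect_identical(corr$R, t(corr$R))
  expect_true(all(diag(corr$P) == 0))
  expect_true(all(abs(corr$R) <= 1, na.rm = TRUE))
  # a constant column breaks only its own pairs
  tab$e <- 1
  corr2 <- suppressWarnings(correlation_matrices(tab))
  expect_true(all(is.na(corr2$R["e", setdiff(colnames(corr2$R), "e")])))
  expect_equal(corr2$R["a", "b"], corr$R["a", "b"])
  # a missing cell drops that variable's pairwise n by one
  tab$b[3] <- NA
  corr3 <- correlation_matrices(tab[1:5])
  expect_equal(corr3$N["a", "b"], 9)
  expect_equal(corr3$N["a", "c"], 10)
})

test_that("permuting subjects leaves the correlation result unchanged", {
  set.seed(5)
  tab <- tibble::tibble(subject_id = as.character(1:12),
                        a = rnorm(12), b = rnorm(12), c = rnorm(12))
  corr <- correlation_matrices(tab)
  corr_perm <- correlation_matrices(tab[sample(12), ])
  expect_equal(corr$R, corr_perm$R)
  expect_equal(corr$P, corr_perm$P)
})

test_that("edges appear exactly when p <= alpha", {
  n <- 15
  make_graph_with_r <- function(r) {
    pr <- pair_with_correlation(n, r, seed = 9)
    tab <- tibble::tibble(subject_id = as.character(1:n),
                          x = pr$x, y = pr$y)
    build_graph(correlation_matrices(tab), alpha = 0.05)
  }
  # r = 0.40 at n = 15: p ~ 0.139 -> no edge
  expect_equal(nrow(make_graph_with_r(0.40)$edges), 0L)
  # r = 0.60 at n = 15: p ~ 0.018 -> edge with weight 0.60
  g <- make_graph_with_r(0.60)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 0.6, tolerance = 1e-9)
  # identical pair: weight-1 edge
  tab <- tibble::tibble(subject_id = as.character(1:n),
                        x = rnorm(n))
  tab$y <- tab$x
  g1 <- build_graph(correlation_matrices(tab), alpha = 0.05)
  expect_equal(g1$edges$weight, 1)
  expect_error(build_graph(correlation_matrices(tab), alpha = 1.2),
               "alpha")
})

test_that("edge sets are monotone in alpha and invariant to affine maps", {
  set.seed(6)
  tab <- tibble::tibble(subject_id = as.character(1:15))
  for (v in paste0("v", 1:12)) tab[[v]] <- rnorm(15)
  corr <- correlation_matrices(tab)
  g05 <- build_graph(corr, alpha = 0.05)
  g01 <- build_graph(corr, alpha = 0.01)
  key <- function(g) paste(g$edges$from, g$edges$to)
  expect_true(all(key(g01) %in% key(g05)))
  # positive rescaling leaves the graph identical; negation flips signed_r
  tab2 <- tab
  tab2$v1 <- 100 * tab2$v1 + 7
  tab2$v2 <- -tab2$v2
  g2 <- build_graph(correlation_matrices(tab2), alpha = 0.05)
  expect_equal(key(g2), key(g05))
  expect_equal(g2$edges$weight, g05$edges$weight, tolerance = 1e-12)
  flip <- xor(g05$edges$from == "v2", g05$edges$to == "v2")
  expect_equal(g2$edges$signed_r,
               ifelse(flip, -g05$edges$signed_r, g05$edges$signed_r),
               tolerance = 1e-12)
})

test_that("graph summaries report counts and density", {
  iso <- graph_from_edges(paste0("n", 1:46), character(0), character(0))
  s <- graph_summary(iso)
  expect_equal(unlist(s[c("nodes", "edges", "density")]),
               c(nodes = 46, edges = 0, density = 0))
  tri <- complete_graph(3)
  expect_equal(graph_summary(tri)$density, 1)
  expect_equal(glance(tri)$edges, 3)
  expect_equal(nrow(tidy(tri)), 3)
})
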