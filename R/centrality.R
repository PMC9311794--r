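#' Centrality computation parameters
#'
#' Defaults follow the conventions of the Gephi graph tool, in which this
#' family of physiological-network studies computes its metrics: betweenness
#' normalized by `(V-1)(V-2)/2` on unweighted shortest paths, eigenvector
#' centrality by 100 power iterations with max-normalization, PageRank with
#' damping 0.85 and convergence epsilon 0.001, and all metrics unweighted
#' unless switched. Weighted betweenness uses distance `1/weight`, so a
#' stronger correlation is a shorter path.
#'
#' @param betweenness_weighted,eigenvector_weighted,pagerank_weighted Use
#'   edge weights (absolute correlations) instead of the unweighted
#'   topology.
#' @param betweenness_normalized Divide betweenness by `(V-1)(V-2)/2`.
#' @param eigenvector_iterations Number of power iterations.
#' @param pagerank_damping Damping factor in (0, 1).
#' @param pagerank_epsilon Convergence threshold on the maximum per-node
#'   change.
#' @return A `centrality_params` list.
#' @export
centrality_params <- function(betweenness_weighted = FALSE,
                              betweenness_normalized = TRUE,
                              eigenvector_iterations = 100L,
                              eigenvector_weighted = FALSE,
                              pagerank_damping = 0.85,
                              pagerank_epsilon = 0.001,
                              pagerank_weighted = FALSE) {
  if (!is.finite(pagerank_damping) || pagerank_damping <= 0 ||
      pagerank_damping >= 1) {
    abort("pagerank_damping must be inside (0, 1)")
  }
  if (eigenvector_iterations < 1) abort("eigenvector_iterations must be >= 1")
  if (pagerank_epsilon <= 0) abort("pagerank_epsilon must be positive")
  structure(list(
    betweenness_weighted = betweenness_weighted,
    betweenness_normalized = betweenness_normalized,
    eigenvector_iterations = as.integer(eigenvector_iterations),
    eigenvector_weighted = eigenvector_weighted,
    pagerank_damping = pagerank_damping,
    pagerank_epsilon = pagerank_epsilon,
    pagerank_weighted = pagerank_weighted
  ), class = "centrality_params")
}

#' Degree centrality
#'
#' The number of edges incident to each node.
#'
#' @param g A `physio_graph`.
#' @return A named integer vector over all nodes (isolated nodes are 0).
#' @export
degree_centrality <- function(g) {
  v <- g$nodes$variable
  deg <- setNames(integer(length(v)), v)
  if (nrow(g$edges)) {
    tab <- table(factor(c(g$edges$from, g$edges$to), levels = v))
    deg[] <- as.integer(tab)
  }
  deg
}

# adjacency list representation: for each node, integer neighbours and the
# corresponding edge distances
adjacency_list <- function(g, distances = FALSE) {
  v <- g$nodes$variable
  n <- length(v)
  nbr <- rep(list(integer(0)), n)
  dst <- rep(list(numeric(0)), n)
  if (nrow(g$edges)) {
    i <- match(g$edges$from, v)
    j <- match(g$edges$to, v)
    d <- if (distances) 1 / g$edges$weight else rep(1, nrow(g$edges))
    for (e in seq_along(i)) {
      nbr[[i[e]]] <- c(nbr[[i[e]]], j[e])
      nbr[[j[e]]] <- c(nbr[[j[e]]], i[e])
      dst[[i[e]]] <- c(dst[[i[e]]], d[e])
      dst[[j[e]]] <- c(dst[[j[e]]], d[e])
    }
  }
  list(nbr = nbr, dst = dst)
}

#' Betweenness centrality (Brandes)
#'
#' The share of shortest paths between node pairs that pass through each
#' node, accumulated with Brandes' pair-dependency algorithm. Shortest paths
#' are unweighted by default; in weighted mode the path length of an edge is
#' `1/weight`. Unreachable pairs contribute nothing. With normalization on,
#' values are divided by `(V-1)(V-2)/2`.
#'
#' @param g A `physio_graph`.
#' @param params A [centrality_params()] object.
#' @return A named numeric vector over all nodes.
#' @export
betweenness_centrality <- function(g, params = centrality_params()) {
  v <- g$nodes$variable
  n <- length(v)
  bc <- setNames(numeric(n), v)
  if (n < 3 || nrow(g$edges) == 0) return(bc)
  if (params$betweenness_weighted && any(g$edges$weight <= 0)) {
    abort("weighted betweenness needs strictly positive edge weights")
  }
  adj <- adjacency_list(g, distances = params$betweenness_weighted)
  for (s in seq_len(n)) {
    if (params$betweenness_weighted) {
      sp <- sssp_dijkstra(adj, s, n)
    } else {
      sp <- sssp_bfs(adj, s, n)
    }
    delta <- numeric(n)
    for (w in rev(sp$order)) {
      for (p in sp$pred[[w]]) {
        delta[p] <- delta[p] + sp$sigma[p] / sp$sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc <- bc / 2  # each undirected pair counted from both endpoints
  if (params$betweenness_normalized) {
    bc <- bc / ((n - 1) * (n - 2) / 2)
  }
  bc
}

sssp_bfs <- function(adj, s, n) {
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  pred <- rep(list(integer(0)), n)
  dist[s] <- 0
  sigma[s] <- 1
  queue <- s
  order <- integer(0)
  while (length(queue)) {
    u <- queue[1]
    queue <- queue[-1]
    order <- c(order, u)
    for (w in adj$nbr[[u]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[u] + 1
        queue <- c(queue, w)
      }
      if (dist[w] == dist[u] + 1) {
        sigma[w] <- sigma[w] + sigma[u]
        pred[[w]] <- c(pred[[w]], u)
      }
    }
  }
  list(order = order, sigma = sigma, pred = pred)
}

sssp_dijkstra <- function(adj, s, n, tol = 1e-12) {
  dist <- rep(Inf, n)
  sigma <- numeric(n)
  pred <- rep(list(integer(0)), n)
  done <- logical(n)
  dist[s] <- 0
  sigma[s] <- 1
  order <- integer(0)
  repeat {
    u <- NA_integer_
    best <- Inf
    for (i in seq_len(n)) {
      if (!done[i] && dist[i] < best) {
        best <- dist[i]
        u <- i
      }
    }
    if (is.na(u)) break
    done[u] <- TRUE
    order <- c(order, u)
    nbrs <- adj$nbr[[u]]
    for (k in seq_along(nbrs)) {
      w <- nbrs[k]
      nd <- dist[u] + adj$dst[[u]][k]
      if (nd < dist[w] - tol) {
        dist[w] <- nd
        sigma[w] <- sigma[u]
        pred[[w]] <- u
      } else if (abs(nd - dist[w]) <= tol * max(1, nd)) {
        sigma[w] <- sigma[w] + sigma[u]
        pred[[w]] <- c(pred[[w]], u)
      }
    }
  }
  list(order = order, sigma = sigma, pred = pred)
}

#' Eigenvector centrality
#'
#' Power iteration on the (optionally weighted) adjacency matrix, shifted by
#' the identity so that the iteration converges on bipartite graphs as well
#' (the shift leaves the eigenvectors unchanged). The result is scaled so
#' the largest value is exactly 1; isolated nodes get 0.
#'
#' @param g A `physio_graph` with at least one edge.
#' @param params A [centrality_params()] object.
#' @return A named numeric vector over all nodes.
#' @export
eigenvector_centrality <- function(g, params = centrality_params()) {
  if (nrow(g$edges) == 0) {
    abort("eigenvector centrality is undefined on an edgeless graph")
  }
  a <- adjacency_matrix(g, weighted = params$eigenvector_weighted)
  n <- nrow(a)
  x <- rep(1, n)
  for (i in seq_len(params$eigenvector_iterations)) {
    x <- as.numeric(a %*% x) + x  # (A + I) x
    x <- x / max(x)
  }
  isolated <- rowSums(a) == 0
  x[isolated] <- 0
  x <- x / max(x)
  setNames(x, g$nodes$variable)
}

#' PageRank
#'
#' The stationary distribution of a damped random walk on the graph, with
#' undirected edges treated as bidirectional. Iterates
#' `p_i = (1 - d)/N + d * sum_j p_j / deg_j` (weighted mode splits each
#' node's probability proportionally to edge weights) until the maximum
#' per-node change drops below `pagerank_epsilon`. Isolated nodes act as
#' dangling nodes and redistribute their probability uniformly. Values sum
#' to 1.
#'
#' @param g A `physio_graph`.
#' @param params A [centrality_params()] object.
#' @return A named numeric vector over all nodes, summing to 1.
#' @export
pagerank <- function(g, params = centrality_params()) {
  v <- g$nodes$variable
  n <- length(v)
  if (n == 0) return(setNames(numeric(0), v))
  a <- adjacency_matrix(g, weighted = params$pagerank_weighted)
  strength <- rowSums(a)
  dangling <- strength == 0
  # column-stochastic transition matrix for non-dangling nodes
  m <- a
  if (any(!dangling)) {
    m[!dangling, ] <- a[!dangling, ] / strength[!dangling]
  }
  m <- t(m)
  d <- params$pagerank_damping
  p <- rep(1 / n, n)
  repeat {
    p_new <- (1 - d) / n + d * (as.numeric(m %*% p) + sum(p[dangling]) / n)
    if (max(abs(p_new - p)) < params$pagerank_epsilon) {
      p <- p_new
      break
    }
    p <- p_new
  }
  setNames(p / sum(p), v)
}

#' All four centrality metrics as a tidy table
#'
#' @param g A `physio_graph`.
#' @param params A [centrality_params()] object.
#' @param metrics Which metrics to compute.
#' @return A tibble with columns `node`, `metric`, `value`. An edgeless
#'   graph yields `NA` eigenvector values rather than an error.
#' @export
centrality <- function(g, params = centrality_params(),
                       metrics = c("degree", "betweenness", "eigenvector",
                                   "pagerank")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  v <- g$nodes$variable
  res <- purrr::map(metrics, function(m) {
    vals <- switch(m,
      degree = as.numeric(degree_centrality(g)),
      betweenness = betweenness_centrality(g, params),
      eigenvector = if (nrow(g$edges) == 0) {
        setNames(rep(NA_real_, length(v)), v)
      } else {
        eigenvector_centrality(g, params)
      },
      pagerank = pagerank(g, params))
    tibble(node = v, metric = m, value = as.numeric(vals))
  })
  dplyr::bind_rows(res)
}
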