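#' Reference centrality values for small graphs
#'
#' Independent re-derivations of the four metrics by methods that share no
#' code with the main implementations: betweenness by exhaustive enumeration
#' of all simple paths, eigenvector by dense eigendecomposition (projecting
#' the uniform start vector onto the dominant eigenspace, which also defines
#' the value on graphs with tied components), PageRank by a direct linear
#' solve of the stationarity equations, and degree by scanning the adjacency
#' matrix. Intended for testing; refuses graphs with more than 9 nodes.
#'
#' @param g A `physio_graph` with at most 9 nodes.
#' @param params A [centrality_params()] object.
#' @return A list with named numeric vectors `degree`, `betweenness`,
#'   `eigenvector` (`NA` on edgeless graphs) and `pagerank`.
#' @export
oracle_suite <- function(g, params = centrality_params()) {
  n <- n_nodes(g)
  if (n > 9) {
    abort("oracle_suite() enumerates paths exhaustively; at most 9 nodes")
  }
  list(
    degree = oracle_degree(g),
    betweenness = oracle_betweenness(g, params),
    eigenvector = oracle_eigenvector(g, params),
    pagerank = oracle_pagerank(g, params)
  )
}

oracle_degree <- function(g) {
  a <- adjacency_matrix(g)
  setNames(as.integer(rowSums(a > 0)), g$nodes$variable)
}

# all simple paths from s to t, as lists of node indices
all_simple_paths <- function(a, s, t) {
  n <- nrow(a)
  paths <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == t) {
      paths[[length(paths) + 1]] <<- path
      return(invisible())
    }
    for (w in which(a[u, ] > 0)) {
      if (!w %in% path) walk(c(path, w))
    }
  }
  walk(s)
  paths
}

oracle_betweenness <- function(g, params = centrality_params()) {
  v <- g$nodes$variable
  n <- length(v)
  bc <- setNames(numeric(n), v)
  if (n < 3) return(bc)
  a <- adjacency_matrix(g, weighted = params$betweenness_weighted)
  len <- function(path) {
    if (params$betweenness_weighted) {
      sum(1 / a[cbind(path[-length(path)], path[-1])])
    } else {
      length(path) - 1
    }
  }
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- all_simple_paths(a, s, t)
      if (!length(paths)) next
      lens <- vapply(paths, len, numeric(1))
      shortest <- paths[abs(lens - min(lens)) <= 1e-9 * max(1, min(lens))]
      inner <- lapply(shortest, function(p) setdiff(p, c(s, t)))
      for (node in seq_len(n)) {
        cnt <- sum(vapply(inner, function(p) node %in% p, logical(1)))
        bc[node] <- bc[node] + cnt / length(shortest)
      }
    }
  }
  if (params$betweenness_normalized) bc <- bc / ((n - 1) * (n - 2) / 2)
  bc
}

oracle_eigenvector <- function(g, params = centrality_params(), tol = 1e-8) {
  v <- g$nodes$variable
  if (nrow(g$edges) == 0) return(setNames(rep(NA_real_, length(v)), v))
  a <- adjacency_matrix(g, weighted = params$eigenvector_weighted)
  es <- eigen(a, symmetric = TRUE)
  lam <- es$values
  top <- which(lam > max(lam) - tol * max(1, abs(max(lam))))
  basis <- es$vectors[, top, drop = FALSE]
  # limit of the power iteration from a uniform nonnegative start
  x <- as.numeric(basis %*% crossprod(basis, rep(1, length(v))))
  x <- abs(x)
  x[rowSums(a) == 0] <- 0
  setNames(x / max(x), v)
}

oracle_pagerank <- function(g, params = centrality_params()) {
  v <- g$nodes$variable
  n <- length(v)
  a <- adjacency_matrix(g, weighted = params$pagerank_weighted)
  strength <- rowSums(a)
  m <- matrix(1 / n, n, n)  # dangling nodes spread uniformly
  for (i in which(strength > 0)) m[, i] <- 0
  for (i in which(strength > 0)) {
    m[which(a[i, ] > 0), i] <- a[i, a[i, ] > 0] / strength[i]
  }
  d <- params$pagerank_damping
  p <- solve(diag(n) - d * m, rep((1 - d) / n, n))
  setNames(p / sum(p), v)
}
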