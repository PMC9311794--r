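#' Pearson correlation with t-distributed p-value
#'
#' The standard product-moment estimate on pairwise-complete observations,
#' with a two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom. Perfect correlation gives p = 0. Pairs with
#' fewer than 3 complete observations or zero variance carry an undefined
#' correlation (`NA`), which upstream code treats as "no edge".
#'
#' @param x,y Numeric vectors of equal length.
#' @return A one-row tibble with `r`, `p` and the pairwise-complete `n`.
#' @export
#' @examples
#' pearson_r_p(c(1, 2, 3, 4), c(1, 3, 2, 4)) # r = 0.8
pearson_r_p <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have the same length")
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3 || var(x[ok]) == 0 || var(y[ok]) == 0) {
    if (n >= 3) warn("undefined correlation: a variable has zero variance")
    return(tibble(r = NA_real_, p = NA_real_, n = n))
  }
  r <- cor(x[ok], y[ok])
  r <- max(-1, min(1, r))
  p <- r_p_value(r, n)
  tibble(r = r, p = p, n = n)
}

r_p_value <- function(r, n) {
  ifelse(abs(r) >= 1, 0,
         2 * pt(abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2,
                lower.tail = FALSE))
}

#' Critical correlation at a significance level
#'
#' The smallest `|r|` that is significant at two-sided level `alpha` for a
#' given number of subjects (inverse of the t transform used for the edge
#' gate). At n = 15 and alpha = 0.05 this is about 0.514.
#'
#' @param n Number of paired observations.
#' @param alpha Two-sided significance level.
#' @return The critical absolute correlation.
#' @export
critical_r <- function(n, alpha = 0.05) {
  tc <- qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(tc^2 + (n - 2))
}

#' All pairwise correlations of a feature table
#'
#' @param features A subjects-by-variables data frame; a `subject_id` column,
#'   if present, is dropped. All remaining columns must be numeric.
#' @return A `correlation_result`: list of symmetric matrices `R` (Pearson
#'   r, unit diagonal), `P` (two-sided p-values, zero diagonal) and `N`
#'   (pairwise-complete counts). Undefined pairs are `NA` in `R` and `P`.
#' @export
correlation_matrices <- function(features) {
  x <- drop_subject_id(features)
  if (!all(vapply(x, is.numeric, logical(1)))) {
    abort("all feature columns must be numeric")
  }
  x <- as.matrix(x)
  if (nrow(x) < 3) abort("need at least 3 subjects for correlation p-values")
  k <- ncol(x)
  ok <- is.finite(x)
  N <- crossprod(ok)
  R <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  # zero-variance or tiny-n pairs -> undefined
  sds <- apply(x, 2, function(col) stats::sd(col[is.finite(col)]))
  undef <- outer(sds == 0 | !is.finite(sds), sds == 0 | !is.finite(sds), "|") |
    (N < 3)
  R[undef] <- NA_real_
  P <- matrix(r_p_value(R, N), k, k)
  P[undef] <- NA_real_
  diag(R) <- 1
  diag(P) <- 0
  dimnames(R) <- dimnames(P) <- dimnames(N) <-
    list(colnames(x), colnames(x))
  if (any(undef[upper.tri(undef)])) {
    warn(sprintf("%d variable pair(s) have undefined correlations",
                 sum(undef[upper.tri(undef)])))
  }
  structure(list(R = R, P = P, N = N), class = "correlation_result")
}

drop_subject_id <- function(features) {
  features <- as_tibble(features)
  features[setdiff(names(features), "subject_id")]
}

#' Build a significance-gated physiological graph
#'
#' Nodes are the catalogue variables; an undirected edge joins two variables
#' when their Pearson correlation is defined and significant at `alpha`
#' (p <= alpha). Edge weight is `|r|` so the centrality metrics operate on
#' nonnegative weights; the signed correlation is kept as the `signed_r`
#' edge attribute. Isolated nodes are retained.
#'
#' @param corr A `correlation_result` from [correlation_matrices()].
#' @param catalogue A catalogue from [scenario_catalogue()], or `NULL` to
#'   take nodes from the matrix column names.
#' @param alpha Significance gate in (0, 1); edges require `p <= alpha`.
#' @return A `physio_graph`: list with a `nodes` tibble (variable and
#'   catalogue annotations), an `edges` tibble (`from`, `to`, `weight`,
#'   `signed_r`, `p`) and the `alpha` used.
#' @export
build_graph <- function(corr, catalogue = NULL, alpha = 0.05) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must be inside (0, 1)")
  }
  vars <- colnames(corr$R)
  if (is.null(catalogue)) {
    nodes <- tibble(variable = vars, family = NA_character_,
                    muscle = NA_character_)
  } else {
    validate_catalogue(catalogue)
    if (!setequal(catalogue$variable, vars)) {
      extra <- setdiff(vars, catalogue$variable)
      miss <- setdiff(catalogue$variable, vars)
      abort(paste0(
        "correlation matrix does not match the catalogue",
        if (length(extra)) paste0("; not in catalogue: ",
                                  paste(extra, collapse = ", ")),
        if (length(miss)) paste0("; missing from matrix: ",
                                 paste(miss, collapse = ", "))))
    }
    nodes <- as_tibble(catalogue[c("variable", "family", "muscle")])
    # keep matrix order aligned to catalogue order
    ord <- match(nodes$variable, vars)
    corr$R <- corr$R[ord, ord]
    corr$P <- corr$P[ord, ord]
    corr$N <- corr$N[ord, ord]
    vars <- nodes$variable
  }
  ut <- which(upper.tri(corr$P) & !is.na(corr$P) & corr$P <= alpha,
              arr.ind = TRUE)
  edges <- tibble(
    from = vars[ut[, 1]],
    to = vars[ut[, 2]],
    weight = abs(corr$R[ut]),
    signed_r = corr$R[ut],
    p = corr$P[ut]
  )
  edges <- edges[edges$weight > 0, ]
  new_physio_graph(nodes, edges, alpha)
}

new_physio_graph <- function(nodes, edges, alpha = NA_real_) {
  if (anyDuplicated(nodes$variable)) abort("duplicate node names")
  if (nrow(edges)) {
    if (any(edges$from == edges$to)) abort("self-loops are not allowed")
    if (any(!is.finite(edges$weight) | edges$weight <= 0 |
            edges$weight > 1 + 1e-12)) {
      abort("edge weights must lie in (0, 1]")
    }
    bad <- !(edges$from %in% nodes$variable) | !(edges$to %in% nodes$variable)
    if (any(bad)) abort("edge endpoints must be catalogue nodes")
  }
  structure(list(nodes = as_tibble(nodes), edges = as_tibble(edges),
                 alpha = alpha),
            class = "physio_graph")
}

#' @export
print.physio_graph <- function(x, ...) {
  cat(sprintf("<physio_graph> %d nodes, %d edges (alpha = %s)\n",
              nrow(x$nodes), nrow(x$edges), format(x$alpha)))
  invisible(x)
}

n_nodes <- function(g) nrow(g$nodes)
n_edges <- function(g) nrow(g$edges)

# 0/1 (or weighted) symmetric adjacency matrix in node order
adjacency_matrix <- function(g, weighted = FALSE) {
  v <- g$nodes$variable
  a <- matrix(0, length(v), length(v), dimnames = list(v, v))
  if (nrow(g$edges)) {
    i <- match(g$edges$from, v)
    j <- match(g$edges$to, v)
    w <- if (weighted) g$edges$weight else 1
    a[cbind(i, j)] <- w
    a[cbind(j, i)] <- w
  }
  a
}

#' Summary counts of a physiological graph
#'
#' @param g A `physio_graph`.
#' @return A one-row tibble: node count, edge count, density
#'   `2E / (V (V - 1))`, and per-family node counts when family annotations
#'   are present.
#' @export
graph_summary <- function(g) {
  v <- n_nodes(g)
  e <- n_edges(g)
  out <- tibble(nodes = v, edges = e,
                density = if (v > 1) 2 * e / (v * (v - 1)) else 0)
  fams <- g$nodes$family
  if (!all(is.na(fams))) {
    counts <- table(fams)
    fam <- as_tibble(as.list(setNames(as.integer(counts),
                                      paste0("n_", names(counts)))))
    out <- dplyr::bind_cols(out, fam)
  }
  out
}

#' @rdname build_graph
#' @param x A `physio_graph`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.physio_graph <- function(x, ...) x$edges

#' @rdname build_graph
#' @param object A `physio_graph`.
#' @exportS3Method generics::glance
glance.physio_graph <- function(object, ...) graph_summary(object)
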