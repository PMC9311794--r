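#' Tie-aware top-5 table by dense rank
#'
#' Centrality values are rounded to the display precision (3 decimals by
#' default, the precision at which the metric tables of this literature
#' report values); nodes whose rounded values coincide share a dense rank,
#' and every node with dense rank <= 5 is returned — so the "top five" may
#' contain far more than five nodes when ties are common.
#'
#' @param values Named numeric vector (node -> centrality value) or a tibble
#'   with `node` and `value` columns.
#' @param round_decimals Decimals defining "similar" values.
#' @param max_rank Largest dense rank kept (5 for a top-5 table).
#' @return A tibble `rank`, `node`, `value` (rounded), `raw_value`, ordered
#'   by rank then node name.
#' @export
#' @examples
#' dense_rank_top5(c(a = 3, b = 2, c = 2, d = 1))
dense_rank_top5 <- function(values, round_decimals = 3, max_rank = 5) {
  if (is.data.frame(values)) {
    values <- setNames(values$value, values$node)
  }
  if (!length(values)) abort("no values to rank")
  rounded <- round(values, round_decimals)
  levels <- sort(unique(rounded), decreasing = TRUE)
  rank <- match(rounded, levels)
  out <- tibble(rank = rank, node = names(values), value = rounded,
                raw_value = as.numeric(values))
  out <- out[out$rank <= max_rank, ]
  out[order(out$rank, out$node), ]
}

#' Per-scenario, per-metric centrality report
#'
#' Bundles a metric's node values with their dense ranks and the tie-aware
#' top-5 groups, mirroring the top-five tables of the source literature's
#' figure panels.
#'
#' @param g A `physio_graph`.
#' @param scenario Scenario label carried into the report.
#' @param metric One of `"degree"`, `"betweenness"`, `"eigenvector"`,
#'   `"pagerank"`.
#' @param params A [centrality_params()] object (echoed in the report).
#' @param round_decimals Tie precision passed to [dense_rank_top5()].
#' @return A `centrality_report` with fields `scenario`, `metric`, `values`,
#'   `top5`, `params`.
#' @export
centrality_report <- function(g, scenario, metric, params = centrality_params(),
                              round_decimals = 3) {
  tab <- centrality(g, params, metrics = metric)
  values <- setNames(tab$value, tab$node)
  top5 <- if (all(is.na(values))) {
    tibble(rank = integer(), node = character(), value = numeric(),
           raw_value = numeric())
  } else {
    dense_rank_top5(values, round_decimals)
  }
  structure(list(scenario = scenario, metric = metric, values = values,
                 top5 = top5, round_decimals = round_decimals,
                 params = params,
                 graph_summary = graph_summary(g)),
            class = "centrality_report")
}

#' @export
print.centrality_report <- function(x, ...) {
  cat(sprintf("<centrality_report> %s / %s — top-5 covers %d nodes\n",
              x$scenario, x$metric, nrow(x$top5)))
  print(x$top5)
  invisible(x)
}

#' @rdname centrality_report
#' @param x A `centrality_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.centrality_report <- function(x, ...) {
  dplyr::mutate(x$top5, scenario = x$scenario, metric = x$metric,
                .before = 1)
}

#' @rdname centrality_report
#' @param object A `centrality_report`.
#' @exportS3Method generics::glance
glance.centrality_report <- function(object, ...) {
  dplyr::bind_cols(
    tibble(scenario = object$scenario, metric = object$metric,
           top5_nodes = nrow(object$top5)),
    object$graph_summary
  )
}

#' Compare two centrality reports
#'
#' Which nodes enter, leave or stay in the top-5 between two scenarios of
#' the same metric, with their rank shifts, plus node/edge count deltas.
#'
#' @param a,b `centrality_report` objects for the same metric.
#' @return A `scenario_comparison` list with tibbles `shared` (node, rank in
#'   each scenario, shift), `entering`, `leaving`, and a one-row `deltas`.
#' @export
compare_scenarios <- function(a, b) {
  if (!identical(a$metric, b$metric)) {
    abort(sprintf("metric mismatch: '%s' vs '%s'", a$metric, b$metric))
  }
  na_ <- a$top5
  nb <- b$top5
  shared_nodes <- sort(intersect(na_$node, nb$node))
  shared <- tibble(
    node = shared_nodes,
    rank_a = na_$rank[match(shared_nodes, na_$node)],
    rank_b = nb$rank[match(shared_nodes, nb$node)]
  )
  shared$shift <- shared$rank_b - shared$rank_a
  deltas <- tibble(
    nodes_a = a$graph_summary$nodes, nodes_b = b$graph_summary$nodes,
    edges_a = a$graph_summary$edges, edges_b = b$graph_summary$edges,
    edge_delta = b$graph_summary$edges - a$graph_summary$edges
  )
  structure(list(
    metric = a$metric,
    scenario_a = a$scenario, scenario_b = b$scenario,
    shared = shared,
    entering = nb[!nb$node %in% na_$node, ],
    leaving = na_[!na_$node %in% nb$node, ],
    deltas = deltas
  ), class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("<scenario_comparison> %s: %s -> %s\n",
              x$metric, x$scenario_a, x$scenario_b))
  cat(sprintf("shared %d, entering %d, leaving %d; edges %d -> %d\n",
              nrow(x$shared), nrow(x$entering), nrow(x$leaving),
              x$deltas$edges_a, x$deltas$edges_b))
  invisible(x)
}

#' Paired Student's t-test
#'
#' The conventional within-subject comparison of a variable between the two
#' exercise conditions: `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1`
#' degrees of freedom and a two-sided p-value. Delegates to
#' [stats::t.test()].
#'
#' @param x,y Per-subject paired values of equal length >= 2.
#' @return A one-row tibble with `estimate` (mean difference x - y), `t`,
#'   `df` and `p`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) {
    abort(sprintf("paired samples differ in length: %d vs %d",
                  length(x), length(y)))
  }
  if (length(x) < 2) abort("need at least 2 pairs")
  d <- x - y
  if (sd(d) == 0 && any(d != 0)) abort("paired differences have zero variance")
  if (sd(d) == 0 && all(d == 0)) {
    # identical samples: no evidence of a difference by convention
    return(tibble(estimate = 0, t = 0, df = length(x) - 1, p = 1))
  }
  fit <- t.test(x, y, paired = TRUE)
  tibble(estimate = unname(fit$estimate), t = unname(fit$statistic),
         df = unname(fit$parameter), p = fit$p.value)
}

#' Distributional assumption checks
#'
#' Shapiro-Wilk normality on each sample and, when two samples are given,
#' Levene's test of variance homogeneity (via `car::leveneTest`). The flags
#' are for reporting only and never gate the analysis pipeline.
#'
#' @param x Numeric sample, n >= 3.
#' @param y Optional second sample for the homogeneity check.
#' @param alpha Flagging level.
#' @return A one-row tibble with the p-values and logical flags
#'   (`normal_x`, and when `y` is given `normal_y`, `homogeneous`).
#' @export
distribution_checks <- function(x, y = NULL, alpha = 0.05) {
  if (length(x) < 3) abort("need n >= 3 for the normality test")
  # shapiro.test is capped at n = 5000
  sw <- function(v) shapiro.test(if (length(v) > 5000) v[1:5000] else v)$p.value
  out <- tibble(shapiro_p_x = sw(x), normal_x = sw(x) > alpha)
  if (!is.null(y)) {
    values <- c(x, y)
    group <- factor(rep(c("x", "y"), c(length(x), length(y))))
    if (sd(values) == 0) {
      lev_p <- 1  # identical constant samples: perfectly homogeneous
    } else {
      lev <- car::leveneTest(values, group, center = stats::median)
      lev_p <- lev[["Pr(>F)"]][1]
      if (is.na(lev_p)) lev_p <- 1
    }
    out$shapiro_p_y <- sw(y)
    out$normal_y <- out$shapiro_p_y > alpha
    out$levene_p <- lev_p
    out$homogeneous <- lev_p > alpha
  }
  out
}
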