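#' Pipeline configuration
#'
#' Bundles everything one four-scenario analysis run needs: either a
#' synthetic-cohort specification or pre-computed feature tables, the
#' significance gate, filter and centrality settings, and the output
#' directory. Validation errors name the offending field.
#'
#' @param synthetic A [synthetic_spec()], or `NULL` when `features` are
#'   supplied directly.
#' @param features Named list of feature tibbles (one per scenario), or
#'   `NULL` to generate them from `synthetic`.
#' @param catalogues Named list of scenario catalogues.
#' @param alpha Edge significance gate.
#' @param filter [filter_params()].
#' @param centrality [centrality_params()].
#' @param round_decimals Tie precision of the top-5 tables.
#' @param out_dir Output directory, or `NULL` for an in-memory run.
#' @param seed Master seed; defaults to the synthetic spec's seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = NULL, features = NULL,
                            catalogues = lapply(
                              setNames(nm = all_scenarios()),
                              scenario_catalogue),
                            alpha = 0.05,
                            filter = filter_params(),
                            centrality = centrality_params(),
                            round_decimals = 3,
                            out_dir = NULL,
                            seed = NULL) {
  if (is.null(synthetic) && is.null(features)) {
    abort("config needs either 'synthetic' or 'features'")
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    abort("config field 'alpha' must be inside (0, 1)")
  }
  if (is.null(seed)) seed <- synthetic$seed
  if (is.null(seed)) abort("config field 'seed' is required")
  structure(list(synthetic = synthetic, features = features,
                 catalogues = catalogues, alpha = alpha, filter = filter,
                 centrality = centrality, round_decimals = round_decimals,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the four-scenario correlation-network pipeline
#'
#' For every scenario: take (or synthesise) the subjects-by-variables
#' feature table, compute all pairwise Pearson correlations, gate edges at
#' `alpha`, compute the four centrality metrics and their tie-aware top-5
#' reports. A scenario that fails is isolated — its error is recorded and
#' the other scenarios still run. With an `out_dir`, features (CSV), graphs
#' (GEXF + GraphML), centrality values (JSON) and reports (JSON + Markdown)
#' are written, together with a manifest carrying the seed and every
#' parameter needed to re-run bit-identically.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result`: list with `scenarios` (per-scenario list of
#'   `features`, `graph`, `summary`, `centrality`, `reports`), `cohort`
#'   (when synthesised), `manifest`, and `errors`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- NULL
  features <- config$features
  if (is.null(features)) {
    cohort <- generate_cohort(config$synthetic, config$catalogues)
    features <- cohort$features
  }
  scenarios <- list()
  errors <- list()
  for (scen in names(config$catalogues)) {
    res <- tryCatch(
      run_scenario(features[[scen]], config$catalogues[[scen]], config),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[scen]] <- conditionMessage(res)
    } else {
      scenarios[[scen]] <- res
    }
  }
  manifest <- list(
    package = "physiograph",
    version = as.character(utils::packageVersion("physiograph")),
    seed = config$seed,
    alpha = config$alpha,
    filter = unclass(config$filter),
    centrality = unclass(config$centrality),
    round_decimals = config$round_decimals,
    scenarios = lapply(scenarios, function(s) {
      as.list(s$summary[c("nodes", "edges", "density")])
    }),
    errors = errors
  )
  out <- structure(list(scenarios = scenarios, cohort = cohort,
                        manifest = manifest, errors = errors),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config)
  out
}

run_scenario <- function(feat, catalogue, config) {
  if (is.null(feat)) abort("no feature table for this scenario")
  if (nrow(feat) == 0) abort("empty feature table")
  corr <- correlation_matrices(feat[c("subject_id", catalogue$variable)])
  g <- build_graph(corr, catalogue, alpha = config$alpha)
  reports <- lapply(
    setNames(nm = c("degree", "betweenness", "eigenvector", "pagerank")),
    function(m) centrality_report(g, catalogue$scenario[1], m,
                                  params = config$centrality,
                                  round_decimals = config$round_decimals))
  list(features = feat, graph = g, summary = graph_summary(g),
       centrality = centrality(g, config$centrality), reports = reports)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (scen in names(x$scenarios)) {
    s <- x$scenarios[[scen]]$summary
    cat(sprintf("  %-14s %d nodes, %d edges (density %.3f)\n",
                scen, s$nodes, s$edges, s$density))
  }
  for (scen in names(x$errors)) {
    cat(sprintf("  %-14s FAILED: %s\n", scen, x$errors[[scen]]))
  }
  invisible(x)
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (scen in names(result$scenarios)) {
    s <- result$scenarios[[scen]]
    base <- file.path(config$out_dir, scen)
    write_feature_table(s$features, paste0(base, "_features.csv"))
    write_graph_file(s$graph, paste0(base, ".gexf"))
    write_graph_file(s$graph, paste0(base, ".graphml"))
    jsonlite::write_json(
      split(setNames(as.list(s$centrality$value), s$centrality$node),
            s$centrality$metric),
      paste0(base, "_centrality.json"), auto_unbox = TRUE, digits = NA)
    report_md <- unlist(lapply(s$reports, top5_markdown))
    writeLines(report_md, paste0(base, "_top5.md"))
    jsonlite::write_json(lapply(s$reports, function(r) {
      list(scenario = r$scenario, metric = r$metric,
           top5 = r$top5, params = unclass(r$params))
    }), paste0(base, "_top5.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

top5_markdown <- function(report) {
  c(sprintf("## %s — %s", report$scenario, report$metric),
    "",
    "| rank | node | value |",
    "| ---- | ---- | ----- |",
    sprintf("| %d | %s | %.3f |", report$top5$rank, report$top5$node,
            report$top5$value),
    "")
}
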