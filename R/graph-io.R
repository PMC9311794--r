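#' Read and write feature tables
#'
#' Feature tables are plain CSV with a `subject_id` column followed by one
#' numeric column per catalogue variable.
#'
#' @param path File path.
#' @param catalogue Optional catalogue; when given, the columns are checked
#'   against it and reordered to match.
#' @return A tibble.
#' @export
read_feature_table <- function(path, catalogue = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"subject_id" %in% names(df)) {
    abort("feature CSV needs a 'subject_id' column")
  }
  if (nrow(df) == 0) abort("feature table is empty")
  out <- as_tibble(df)
  if (!is.null(catalogue)) {
    unmatched <- setdiff(setdiff(names(out), "subject_id"),
                         catalogue$variable)
    missing <- setdiff(catalogue$variable, names(out))
    if (length(unmatched) || length(missing)) {
      abort(paste0(
        "feature columns do not match the catalogue",
        if (length(unmatched)) paste0("; unmatched: ",
                                      paste(unmatched, collapse = ", ")),
        if (length(missing)) paste0("; missing: ",
                                    paste(missing, collapse = ", "))))
    }
    out <- out[c("subject_id", catalogue$variable)]
  }
  out
}

#' @rdname read_feature_table
#' @param features A feature tibble.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

num_attr <- function(x) sprintf("%.17g", x)

#' Write a graph to GEXF or GraphML
#'
#' GEXF is the native format of the Gephi tool in which this literature's
#' networks are laid out and inspected; GraphML is the mirror for other
#' tools. Both carry the edge `weight` (absolute correlation) and `signed_r`
#' attributes and the node `family`/`muscle` annotations at full double
#' precision, so a write-read round trip is exact to 1e-9 and beyond.
#'
#' @param g A `physio_graph`.
#' @param path Output file path.
#' @param format `"gexf"` or `"graphml"`; defaults from the file extension.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(g, path, format = c("auto", "gexf", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE))
      "graphml" else "gexf"
  }
  if (format == "gexf") write_gexf(g, path) else write_graphml(g, path)
  invisible(path)
}

write_gexf <- function(g, path) {
  doc <- xml2::xml_new_root(
    "gexf", xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected",
                               mode = "static")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "family",
                      type = "string")
  xml2::xml_add_child(attrs, "attribute", id = "1", title = "muscle",
                      type = "string")
  eattrs <- xml2::xml_add_child(graph, "attributes", class = "edge")
  xml2::xml_add_child(eattrs, "attribute", id = "0", title = "signed_r",
                      type = "double")
  nodes <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(nrow(g$nodes))) {
    nd <- xml2::xml_add_child(nodes, "node", id = g$nodes$variable[i],
                              label = g$nodes$variable[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0",
                        value = g$nodes$family[i] %|na|% "")
    xml2::xml_add_child(av, "attvalue", `for` = "1",
                        value = g$nodes$muscle[i] %|na|% "")
  }
  edges <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(g$edges))) {
    ed <- xml2::xml_add_child(edges, "edge", id = as.character(i - 1),
                              source = g$edges$from[i],
                              target = g$edges$to[i],
                              weight = num_attr(g$edges$weight[i]))
    av <- xml2::xml_add_child(ed, "attvalues")
    xml2::xml_add_child(av, "attvalue", `for` = "0",
                        value = num_attr(g$edges$signed_r[i]))
  }
  xml2::write_xml(doc, path)
}

`%|na|%` <- function(x, y) if (is.na(x)) y else x

write_graphml <- function(g, path) {
  doc <- xml2::xml_new_root(
    "graphml", xmlns = "http://graphml.graphdrawing.org/xmlns")
  xml2::xml_add_child(doc, "key", id = "family", `for` = "node",
                      attr.name = "family", attr.type = "string")
  xml2::xml_add_child(doc, "key", id = "muscle", `for` = "node",
                      attr.name = "muscle", attr.type = "string")
  xml2::xml_add_child(doc, "key", id = "weight", `for` = "edge",
                      attr.name = "weight", attr.type = "double")
  xml2::xml_add_child(doc, "key", id = "signed_r", `for` = "edge",
                      attr.name = "signed_r", attr.type = "double")
  graph <- xml2::xml_add_child(doc, "graph", id = "G",
                               edgedefault = "undirected")
  for (i in seq_len(nrow(g$nodes))) {
    nd <- xml2::xml_add_child(graph, "node", id = g$nodes$variable[i])
    xml2::xml_set_text(xml2::xml_add_child(nd, "data", key = "family"),
                       g$nodes$family[i] %|na|% "")
    xml2::xml_set_text(xml2::xml_add_child(nd, "data", key = "muscle"),
                       g$nodes$muscle[i] %|na|% "")
  }
  for (i in seq_len(nrow(g$edges))) {
    ed <- xml2::xml_add_child(graph, "edge", source = g$edges$from[i],
                              target = g$edges$to[i])
    xml2::xml_set_text(xml2::xml_add_child(ed, "data", key = "weight"),
                       num_attr(g$edges$weight[i]))
    xml2::xml_set_text(xml2::xml_add_child(ed, "data", key = "signed_r"),
                       num_attr(g$edges$signed_r[i]))
  }
  xml2::write_xml(doc, path)
}

#' Read a graph written by [write_graph_file()]
#'
#' @param path A `.gexf` or `.graphml` file.
#' @return A `physio_graph`.
#' @export
read_graph_file <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(paste0("malformed XML: ",
                                                   conditionMessage(e))))
  root <- xml2::xml_name(doc)
  if (root == "gexf") read_gexf(doc) else if (root == "graphml")
    read_graphml(doc) else abort(sprintf("unrecognised graph format '%s'",
                                         root))
}

read_gexf <- function(doc) {
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nd <- xml2::xml_find_all(doc, ".//g:node", ns)
  att <- function(node, id) {
    v <- xml2::xml_find_first(
      node, sprintf(".//g:attvalue[@for='%s']", id), ns)
    xml2::xml_attr(v, "value")
  }
  nodes <- tibble(
    variable = xml2::xml_attr(nd, "id"),
    family = vapply(nd, att, character(1), "0"),
    muscle = vapply(nd, att, character(1), "1")
  )
  nodes$family[nodes$family == ""] <- NA_character_
  nodes$muscle[nodes$muscle == ""] <- NA_character_
  ed <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edges <- tibble(
    from = xml2::xml_attr(ed, "source"),
    to = xml2::xml_attr(ed, "target"),
    weight = as.numeric(xml2::xml_attr(ed, "weight")),
    signed_r = as.numeric(vapply(ed, att, character(1), "0"))
  )
  new_physio_graph(nodes, edges)
}

read_graphml <- function(doc) {
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nd <- xml2::xml_find_all(doc, ".//g:node", ns)
  dat <- function(node, key) {
    v <- xml2::xml_find_first(node, sprintf(".//g:data[@key='%s']", key), ns)
    xml2::xml_text(v)
  }
  nodes <- tibble(
    variable = xml2::xml_attr(nd, "id"),
    family = vapply(nd, dat, character(1), "family"),
    muscle = vapply(nd, dat, character(1), "muscle")
  )
  nodes$family[nodes$family == ""] <- NA_character_
  nodes$muscle[nodes$muscle == ""] <- NA_character_
  ed <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edges <- tibble(
    from = xml2::xml_attr(ed, "source"),
    to = xml2::xml_attr(ed, "target"),
    weight = as.numeric(vapply(ed, dat, character(1), "weight")),
    signed_r = as.numeric(vapply(ed, dat, character(1), "signed_r"))
  )
  new_physio_graph(nodes, edges)
}
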