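#' @title Network and table exporters
#' @name exporters
#' @description GraphML (via igraph), GEXF 1.2 (written directly; igraph has
#'   no GEXF writer) and deterministic CSV outputs. All CSVs are sorted so
#'   repeated runs are byte-identical and diffable.
NULL

#' Convert a `dn_network` to an igraph graph
#'
#' Node attributes: `actor_type`, `statement_frequency`, and `coalition`
#' when an assignment is supplied. Edge attributes: `weight`, `co_support`,
#' `co_reject`, `diverge`.
#'
#' @param network a `dn_network`.
#' @param assignment optional named coalition vector or `dn_partition`.
#' @return an undirected igraph object.
#' @export
as_igraph <- function(network, assignment = NULL) {
  stopifnot(inherits(network, "dn_network"))
  nodes <- network$nodes
  names(nodes)[1] <- "name"
  if (!is.null(assignment)) {
    if (inherits(assignment, "dn_partition")) assignment <- assignment$assignment
    nodes$coalition <- as.integer(assignment[nodes$name])
  }
  igraph::graph_from_data_frame(network$edges, directed = FALSE, vertices = nodes)
}

#' Write a network as GraphML
#' @inheritParams as_igraph
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path, assignment = NULL) {
  g <- as_igraph(network, assignment)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Write a network as GEXF 1.2
#' @inheritParams write_network_graphml
#' @return `path`, invisibly.
#' @export
write_network_gexf <- function(network, path, assignment = NULL) {
  stopifnot(inherits(network, "dn_network"))
  nodes <- network$nodes
  if (!is.null(assignment)) {
    if (inherits(assignment, "dn_partition")) assignment <- assignment$assignment
    nodes$coalition <- as.integer(assignment[nodes$actor])
  }
  edges <- network$edges
  has_coal <- "coalition" %in% names(nodes)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph defaultedgetype="undirected" mode="static">',
    '    <attributes class="node">',
    '      <attribute id="0" title="actor_type" type="string"/>',
    '      <attribute id="1" title="statement_frequency" type="integer"/>',
    if (has_coal) '      <attribute id="2" title="coalition" type="integer"/>',
    '    </attributes>',
    '    <nodes>')
  node_xml <- vapply(seq_len(nrow(nodes)), function(i) {
    att <- sprintf('<attvalue for="0" value="%s"/><attvalue for="1" value="%d"/>%s',
                   xml_escape(nodes$actor_type[i]), nodes$statement_frequency[i],
                   if (has_coal) sprintf('<attvalue for="2" value="%d"/>', nodes$coalition[i]) else "")
    sprintf('      <node id="%s" label="%s"><attvalues>%s</attvalues></node>',
            xml_escape(nodes$actor[i]), xml_escape(nodes$actor[i]), att)
  }, character(1))
  edge_xml <- if (nrow(edges) > 0) vapply(seq_len(nrow(edges)), function(i) {
    sprintf(paste0('      <edge id="e%d" source="%s" target="%s" weight="%.10g">',
                   '<attvalues><attvalue for="co_support" value="%d"/>',
                   '<attvalue for="co_reject" value="%d"/>',
                   '<attvalue for="diverge" value="%d"/></attvalues></edge>'),
            i, xml_escape(edges$actor_a[i]), xml_escape(edges$actor_b[i]),
            edges$weight[i], edges$co_support[i], edges$co_reject[i], edges$diverge[i])
  }, character(1)) else character(0)
  out <- c(out, node_xml, "    </nodes>", "    <edges>", edge_xml,
           "    </edges>", "  </graph>", "</gexf>")
  writeLines(out[!vapply(out, is.null, logical(1))], path, useBytes = TRUE)
  invisible(path)
}

#' Write the edge list as CSV
#' @param network a `dn_network`.
#' @param path output path (`actor_a,actor_b,weight,co_support,co_reject,diverge`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "dn_network"))
  utils::write.csv(network$edges, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a coalition partition as CSV
#' @param partition a `dn_partition` (or named assignment vector).
#' @param path output path (`actor,coalition_id`), actors sorted.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  assignment <- if (inherits(partition, "dn_partition")) partition$assignment else partition
  df <- data.frame(actor = names(assignment), coalition_id = as.integer(assignment),
                   stringsAsFactors = FALSE)
  df <- df[order(df$actor, method = "radix"), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write an external-ratio table as CSV
#'
#' Columns mirror the embeddedness table of the study (actor, total ties,
#' within-cluster ties, external ratio); the ratio is rounded to 2 decimals
#' for display.
#'
#' @param tab output of [external_ratio_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_external_ratio <- function(tab, path) {
  tab$external_ratio <- sprintf("%.2f", tab$external_ratio)
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a windowed concept-frequency table as CSV
#' @param tab output of [concept_frequency_by_window()] (or
#'   [concept_frequency()], which gains empty window columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_concept_table <- function(tab, path) {
  if (!"window_start" %in% names(tab)) {
    w <- attr(tab, "window")
    tab <- cbind(data.frame(window_start = if (is.null(w)) "" else format(w[1]),
                            window_end = if (is.null(w)) "" else format(w[2]),
                            stringsAsFactors = FALSE),
                 as.data.frame(tab))
  }
  tab$contestedness <- round(tab$contestedness, 4)
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
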