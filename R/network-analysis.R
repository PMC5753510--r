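# Typed interaction networks and degree-based hub detection.
#
# Edges carry an interaction type (enzyme-enzyme relation, protein-protein
# interaction, gene-expression interaction, or literature co-citation) and a
# polarity (association / inhibition / activation). The merged graph is
# undirected and simple: parallel edges across evidence types collapse into
# one edge whose attributes hold the set of types.

EDGE_TYPES <- c("enzyme_enzyme", "protein_protein", "gene_expression", "cocitation")
EDGE_POLARITIES <- c("association", "inhibition", "activation")

validate_edges <- function(edges) {
  need <- c("source", "target", "type", "polarity")
  miss <- setdiff(need, names(edges))
  if (length(miss)) stopf("edge table is missing columns: %s", paste(miss, collapse = ", "))
  for (col in c("source", "target")) edges[[col]] <- toupper(trimws(as.character(edges[[col]])))
  bad <- which(!edges$type %in% EDGE_TYPES)
  if (length(bad)) stopf("edge row %d: unknown interaction type '%s'", bad[1], edges$type[bad[1]])
  bad <- which(!edges$polarity %in% EDGE_POLARITIES)
  if (length(bad)) stopf("edge row %d: unknown polarity '%s'", bad[1], edges$polarity[bad[1]])
  bad <- which(!nzchar(edges$source) | !nzchar(edges$target))
  if (length(bad)) stopf("edge row %d: empty endpoint symbol", bad[1])
  edges
}

#' Build an undirected typed interaction network
#'
#' Self-loops are dropped with a warning. Duplicate edges between the same
#' node pair (including across interaction types) merge into one simple
#' edge whose `type` and `polarity` attributes are semicolon-joined sets.
#'
#' @param edges Data frame with columns `source`, `target`, `type`
#'   (`enzyme_enzyme`, `protein_protein`, `gene_expression`, `cocitation`)
#'   and `polarity` (`association`, `inhibition`, `activation`).
#' @param nodes Optional extra node symbols to include even when isolated.
#' @return An undirected simple [igraph][igraph::igraph-package] graph with
#'   merged `type`/`polarity` edge attributes.
#' @export
build_network <- function(edges, nodes = NULL) {
  nodes <- if (is.null(nodes)) character(0) else toupper(trimws(nodes))
  if (is.null(edges) || nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    if (length(nodes)) g <- igraph::add_vertices(g, length(nodes), name = unique(nodes))
    return(g)
  }
  edges <- validate_edges(edges)
  loops <- edges$source == edges$target
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop edge(s)", sum(loops)), call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges) == 0L) return(build_network(NULL, nodes = nodes))
  a <- pmin(edges$source, edges$target)
  b <- pmax(edges$source, edges$target)
  key <- paste(a, b, sep = "\r")
  agg_attr <- function(x) vapply(split(x, key), function(v)
    paste(sort(unique(v)), collapse = ";"), character(1))
  types <- agg_attr(edges$type)
  pols <- agg_attr(edges$polarity)
  uk <- names(types)
  ends <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ends[, 1], to = ends[, 2],
               type = unname(types), polarity = unname(pols),
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = sort(unique(c(ends[, 1], ends[, 2], nodes))))
  g
}

#' Node connectivity (degree)
#'
#' Degree of every node in the merged simple graph.
#'
#' @param graph Graph from [build_network()].
#' @return Named integer vector, one entry per node.
#' @export
connectivity <- function(graph) {
  deg <- igraph::degree(graph, loops = FALSE)
  stats::setNames(as.integer(deg), names(deg))
}

#' Degree z-test for hub genes
#'
#' Standardises each node's degree against the empirical degree
#' distribution, `z = (k_i - mean(k)) / sd(k)` (sample SD), and reports the
#' one-sided upper-tail normal probability `p = 1 - pnorm(z)`: small p
#' marks nodes far more connected than typical, the operational definition
#' of a hub. On a regular graph the degree SD is zero; all z are then
#' defined as 0 with p = 0.5 and the result is flagged degenerate.
#'
#' @param degrees Named numeric vector of node degrees (>= 2 nodes), e.g.
#'   from [connectivity()].
#' @return Data frame `node`, `degree`, `z`, `p` sorted by ascending p
#'   (ties: descending degree, then node name), with logical attribute
#'   `"degenerate"`.
#' @export
hub_test <- function(degrees) {
  if (length(degrees) < 2L) stopf("hub test requires at least two nodes")
  if (is.null(names(degrees))) names(degrees) <- paste0("node_", seq_along(degrees))
  s <- stats::sd(degrees)
  degenerate <- !is.finite(s) || s == 0
  z <- if (degenerate) rep(0, length(degrees)) else (degrees - mean(degrees)) / s
  p <- if (degenerate) rep(0.5, length(degrees)) else stats::pnorm(z, lower.tail = FALSE)
  out <- data.frame(node = names(degrees), degree = as.integer(degrees),
                    z = z, p = p, stringsAsFactors = FALSE)
  out <- out[order(out$p, -out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "degenerate") <- degenerate
  out
}

#' Export / import a network as GraphML
#'
#' The GraphML carries the merged `type` and `polarity` edge attributes and
#' round-trips losslessly through [read_network()].
#'
#' @param graph Graph from [build_network()].
#' @param path File path.
#' @return `export_graph()` returns the path invisibly; `read_network()`
#'   returns the graph.
#' @export
export_graph <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname export_graph
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Read a typed edge list from TSV
#'
#' Expects columns `source`, `target`, `type`, `polarity`; malformed rows
#' are reported with their row number.
#'
#' @param path File path.
#' @return Validated edge data frame.
#' @export
read_edges_tsv <- function(path) {
  validate_edges(read_tsv_file(path))
}

#' @rdname read_edges_tsv
#' @param edges Edge data frame.
#' @export
write_edges_tsv <- function(edges, path) {
  write_tsv_file(validate_edges(edges), path)
}
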