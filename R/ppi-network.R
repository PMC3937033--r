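#' Weighted undirected PPI network
#'
#' A simple undirected graph whose nodes are gene identifiers and whose
#' links carry a non-negative weight. Stored as a node vector plus a
#' canonical edge table: endpoints of every link are ordered
#' lexicographically (`from < to`) and the table is sorted by
#' `(from, to)`, so link identity is deterministic across runs and
#' platforms -- downstream tie-breaking depends on this.
#'
#' @param nodes character vector of gene identifiers (duplicates removed).
#' @param edges data.frame with columns `from`, `to` and optionally
#'   `weight` (defaults to 1). Self-loops are rejected; duplicate
#'   unordered pairs are rejected (collapse them upstream with
#'   [load_edge_list()]).
#' @return An object of class `ppi_network` with elements `nodes`
#'   (sorted character vector) and `edges` (canonical edge table).
#' @export
ppi_network <- function(nodes, edges = NULL) {
  nodes <- sort(unique(as.character(nodes)))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    from <- as.character(edges$from)
    to <- as.character(edges$to)
    weight <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else rep(1, length(from))
    if (any(from == to)) stop("self-loops are not allowed in a ppi_network")
    if (any(weight < 0, na.rm = TRUE)) stop("link weights must be non-negative")
    swap <- from > to
    tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
    key <- paste(from, to, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate links; collapse the edge list first")
    o <- order(from, to, method = "radix")
    edges <- data.frame(from = from[o], to = to[o], weight = weight[o],
                        stringsAsFactors = FALSE)
    missing_nodes <- setdiff(c(edges$from, edges$to), nodes)
    if (length(missing_nodes)) nodes <- sort(unique(c(nodes, missing_nodes)))
  }
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d links\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of links in a network
#' @param network a [ppi_network()].
#' @return integer link count.
#' @export
n_links <- function(network) nrow(network$edges)

#' Canonical link identifiers ("from|to", from < to)
#' @param network a [ppi_network()].
#' @return character vector, one id per link, in canonical order.
#' @export
link_ids <- function(network) {
  if (nrow(network$edges) == 0L) return(character())
  paste(network$edges$from, network$edges$to, sep = "|")
}

#' Convert to an igraph graph
#'
#' Nodes without links are kept as isolated vertices; weights are carried
#' in the `weight` edge attribute.
#'
#' @param network a [ppi_network()].
#' @return an undirected `igraph` graph.
#' @export
as_igraph <- function(network) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(network$nodes), name = network$nodes)
  if (nrow(network$edges) > 0L) {
    idx <- rbind(match(network$edges$from, network$nodes),
                 match(network$edges$to, network$nodes))
    g <- igraph::add_edges(g, as.vector(idx), weight = network$edges$weight)
  }
  g
}

#' Node degrees and strengths
#'
#' Degree is the number of incident links; strength is the sum of
#' incident link weights (equal to the sole link weight for a degree-1
#' node).
#'
#' @param network a [ppi_network()].
#' @return data.frame with columns `node`, `degree`, `strength`, one row
#'   per node in node order.
#' @export
node_strengths <- function(network) {
  deg <- stats::setNames(integer(length(network$nodes)), network$nodes)
  str <- stats::setNames(numeric(length(network$nodes)), network$nodes)
  if (nrow(network$edges) > 0L) {
    dt <- tapply(c(rep(1L, nrow(network$edges)), rep(1L, nrow(network$edges))),
                 c(network$edges$from, network$edges$to), sum)
    deg[names(dt)] <- as.integer(dt)
    st <- tapply(c(network$edges$weight, network$edges$weight),
                 c(network$edges$from, network$edges$to), sum)
    str[names(st)] <- as.numeric(st)
  }
  data.frame(node = network$nodes, degree = unname(deg),
             strength = unname(str), stringsAsFactors = FALSE)
}

#' Drop a set of links from a network
#'
#' @param network a [ppi_network()].
#' @param ids canonical link identifiers (see [link_ids()]).
#' @param drop_isolated drop nodes left without any link?
#' @return a new `ppi_network`.
#' @export
drop_links <- function(network, ids, drop_isolated = FALSE) {
  keep <- !(link_ids(network) %in% ids)
  edges <- network$edges[keep, , drop = FALSE]
  nodes <- network$nodes
  if (drop_isolated) nodes <- sort(unique(c(edges$from, edges$to)))
  ppi_network(nodes, edges)
}

#' Induced subnetwork on the nodes that have at least one link
#' @param network a [ppi_network()].
#' @return a `ppi_network` without isolated nodes.
#' @export
active_subnetwork <- function(network) {
  ppi_network(unique(c(network$edges$from, network$edges$to)), network$edges)
}

#' A gene set
#'
#' @param name label for the set.
#' @param members character vector of gene identifiers.
#' @return list with `name` and sorted unique `members`, class `gene_set`.
#' @export
gene_set <- function(name, members) {
  members <- sort(unique(as.character(members)))
  structure(list(name = as.character(name), members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$members)))
  invisible(x)
}
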