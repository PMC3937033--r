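#' Randomize the weights of a fraction of links
#'
#' Selects `round(fraction * L)` links uniformly at random and permutes
#' their weights among themselves (or, optionally, resamples them with
#' replacement from the selected weights). Topology and unselected
#' weights are untouched; in permutation mode the weight multiset of
#' the whole network is conserved exactly.
#'
#' @param network a [ppi_network()].
#' @param fraction fraction of links to randomize, in `[0, 1]`.
#' @param seed RNG seed.
#' @param method `"permute"` (default) or `"resample"`.
#' @return a new [ppi_network()].
#' @export
randomize_weights <- function(network, fraction, seed,
                              method = c("permute", "resample")) {
  method <- match.arg(method)
  stopifnot(fraction >= 0, fraction <= 1)
  L <- nrow(network$edges)
  m <- round(fraction * L)
  edges <- network$edges
  if (m > 0L) {
    set.seed(seed)
    sel <- sample(L, m)
    w <- edges$weight[sel]
    edges$weight[sel] <- if (method == "permute") w[sample(m)] else {
      sample(w, m, replace = TRUE)
    }
  }
  out <- ppi_network(network$nodes, edges)
  for (a in c("anchors", "backbone_nodes", "backbone_links")) {
    if (!is.null(attr(network, a))) attr(out, a) <- attr(network, a)
  }
  out
}

#' Topology statistics of a filtered network
#'
#' Computed on the subnetwork of nodes that still have at least one
#' link. Path length is the mean shortest-path length (hop count) over
#' connected node pairs only; betweenness is unweighted; the clustering
#' coefficient is the mean local clustering with value 0 for nodes of
#' degree < 2.
#'
#' @param network a [ppi_network()].
#' @return one-row data.frame: `degree`, `path_length`,
#'   `node_betweenness`, `link_betweenness`, `clustering`, `degenerate`
#'   (1 when the network has no links and all statistics are 0).
#' @export
network_statistics <- function(network) {
  if (nrow(network$edges) == 0L) {
    return(data.frame(degree = 0, path_length = 0, node_betweenness = 0,
                      link_betweenness = 0, clustering = 0, degenerate = 1L))
  }
  g <- as_igraph(active_subnetwork(network))
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  data.frame(
    degree = mean(igraph::degree(g)),
    path_length = igraph::mean_distance(g, weights = NA, directed = FALSE,
                                        unconnected = TRUE),
    node_betweenness = mean(igraph::betweenness(g, directed = FALSE,
                                                weights = NA)),
    link_betweenness = mean(igraph::edge_betweenness(g, directed = FALSE,
                                                     weights = NA)),
    clustering = mean(cc),
    degenerate = 0L)
}

#' Link-weight-randomization (LWRN) robustness experiment
#'
#' For each fraction f and iteration: randomize the weights of a
#' fraction f of links, recompute the significance p-values on the
#' randomized network, re-run the connectivity-constrained filter with
#' the same anchor constraints, and record topology statistics of the
#' filtered result plus its link intersection with the reference
#' filtered network. Per-iteration seeds are derived from the master
#' seed and the (fraction, iteration) index, so the whole experiment is
#' reproducible from one integer.
#'
#' @param network the input [ppi_network()] (same network the reference
#'   was filtered from).
#' @param reference a [filter_network()] result on `network`.
#' @param constraints the anchor constraints used for the reference.
#' @param fractions fractions of links to randomize (default 0.1-0.9).
#' @param iterations iterations per fraction (default 30).
#' @param seed master seed.
#' @param bin_width significance bin width (default 1).
#' @param method weight-randomization method, see [randomize_weights()].
#' @return data.frame with one row per (fraction, iteration) and one
#'   `iteration = "mean"` row per fraction; columns `fraction`,
#'   `iteration`, the five topology statistics, `intersection_count`
#'   and `intersection_fraction` (relative to the reference link set),
#'   and `degenerate`.
#' @export
lwrn_experiment <- function(network, reference, constraints,
                            fractions = seq(0.1, 0.9, by = 0.1),
                            iterations = 30L, seed = 1L, bin_width = 1,
                            method = "permute") {
  ref_ids <- link_ids(reference$network)
  rows <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    iter_rows <- vector("list", iterations)
    for (it in seq_len(iterations)) {
      it_seed <- (seed + 7919L * fi + it) %% .Machine$integer.max
      lwrn <- randomize_weights(network, f, seed = it_seed, method = method)
      sig <- gloss_pvalues(lwrn, bin_width = bin_width)
      res <- filter_network(lwrn, sig, constraints, record_topology = FALSE)
      stats <- network_statistics(res$network)
      ids <- link_ids(res$network)
      stats$intersection_count <- length(intersect(ids, ref_ids))
      stats$intersection_fraction <- if (length(ref_ids)) {
        stats$intersection_count / length(ref_ids)
      } else 0
      iter_rows[[it]] <- cbind(data.frame(fraction = f,
                                          iteration = as.character(it),
                                          stringsAsFactors = FALSE), stats)
    }
    block <- do.call(rbind, iter_rows)
    num <- block[, !(names(block) %in% c("fraction", "iteration")),
                 drop = FALSE]
    mean_row <- cbind(data.frame(fraction = f, iteration = "mean",
                                 stringsAsFactors = FALSE),
                      as.data.frame(as.list(colMeans(num))))
    rows[[fi]] <- rbind(block, mean_row)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an LWRN report as TSV
#' @param report result of [lwrn_experiment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lwrn_report <- function(report, path) {
  df <- report
  num <- vapply(df, is.numeric, logical(1))
  for (col in names(df)[num]) df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
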