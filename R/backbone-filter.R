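#' Anchor connectivity constraint
#'
#' @param set_a,set_b non-empty [gene_set()]s (e.g. the receptor-complex
#'   genes and a downstream signalling pathway's components).
#' @return list of class `anchor_constraint`.
#' @export
anchor_constraint <- function(set_a, set_b) {
  if (length(set_a$members) == 0L || length(set_b$members) == 0L) {
    stop("anchor sets must be non-empty")
  }
  structure(list(set_a = set_a, set_b = set_b), class = "anchor_constraint")
}

#' Is any member of one anchor set connected to any member of the other?
#'
#' True iff some path joins a member of `constraint$set_a` to a member
#' of `constraint$set_b` (trivially true when the sets share a gene).
#'
#' @param network a [ppi_network()].
#' @param constraint an [anchor_constraint()]; every anchor gene must be
#'   a node of the network.
#' @return logical scalar.
#' @export
anchors_connected <- function(network, constraint) {
  a <- constraint$set_a$members
  b <- constraint$set_b$members
  missing <- setdiff(c(a, b), network$nodes)
  if (length(missing)) {
    stop("anchor gene(s) absent from the network: ",
         paste(missing, collapse = ", "))
  }
  if (length(intersect(a, b))) return(TRUE)
  comp <- igraph::components(as_igraph(network))$membership
  any(comp[a] %in% comp[b])
}

#' Topology record of a (partially filtered) network
#'
#' Percolation-style summary relative to the original network:
#' fraction of links removed, fraction of nodes left without any link,
#' diameter of the largest connected component (longest shortest path;
#' defined on the giant component so it stays finite as the network
#' fragments), relative giant-component size n_rel = n/N, and the mean
#' node count of the non-giant ("isolated") components, singletons
#' included (0 when only the giant component exists).
#'
#' @param network current [ppi_network()].
#' @param original the unfiltered [ppi_network()] it descends from
#'   (defaults to `network` itself).
#' @return one-row data.frame with columns `links_removed_fraction`,
#'   `nodes_isolated_fraction`, `diameter`, `giant_relative_size`,
#'   `mean_isolated_component_size`.
#' @export
topology_record <- function(network, original = network) {
  N <- length(original$nodes)
  if (N == 0L) {
    return(data.frame(links_removed_fraction = 0, nodes_isolated_fraction = 0,
                      diameter = 0, giant_relative_size = 0,
                      mean_isolated_component_size = 0))
  }
  L0 <- nrow(original$edges)
  L <- nrow(network$edges)
  linked <- unique(c(network$edges$from, network$edges$to))
  g <- as_igraph(network)
  comp <- igraph::components(g)
  sizes <- comp$csize
  giant_idx <- which.max(sizes)
  giant <- sizes[giant_idx]
  others <- sizes[-giant_idx]
  diam <- if (giant <= 1L) 0 else {
    sub <- igraph::induced_subgraph(g, which(comp$membership == giant_idx))
    igraph::diameter(sub, directed = FALSE, weights = NA)
  }
  data.frame(
    links_removed_fraction = if (L0 > 0) (L0 - L) / L0 else 0,
    nodes_isolated_fraction = (N - length(linked)) / N,
    diameter = diam,
    giant_relative_size = giant / N,
    mean_isolated_component_size = if (length(others)) mean(others) else 0)
}

#' Connectivity-constrained descending-p-value filtering
#'
#' The backbone-extraction procedure: repeatedly select the link with
#' the largest p-value, remove it, and check that every anchor
#' constraint still holds; if connectivity between an anchor pair is
#' lost, the link is returned to the network and filtering stops. A
#' topology record is taken after every accepted removal. Ties on the
#' p-value are broken by ascending weight, then by lexicographic link
#' identifier, so runs are fully reproducible.
#'
#' @param network a [ppi_network()].
#' @param significance [gloss_pvalues()] table covering every link.
#' @param constraints a single [anchor_constraint()] or a list of them.
#' @param mode `"joint"` (all constraints enforced simultaneously in
#'   one pass; the first violated constraint stops the run) or
#'   `"sequential"` (one full pass per constraint, in list order).
#' @param record_topology take a [topology_record()] after every
#'   accepted removal? (Disable for speed in repeated experiments.)
#' @return list of class `filter_result`: `network` (surviving
#'   [ppi_network()]), `trace` (data.frame `step`, `from`, `to`,
#'   `p_value`, `accepted`), `stop_link` (canonical id of the restored
#'   link, or `NA`), `topology` (data.frame, one row per accepted
#'   removal, plus a step-0 row for the input network), `stop_reason`
#'   (`"constraint_violated"` or `"links_exhausted"`).
#' @export
filter_network <- function(network, significance, constraints,
                           mode = c("joint", "sequential"),
                           record_topology = TRUE) {
  mode <- match.arg(mode)
  if (inherits(constraints, "anchor_constraint")) constraints <- list(constraints)
  if (mode == "sequential") {
    res <- NULL
    net <- network
    for (ct in constraints) {
      res_i <- filter_network(net, significance, list(ct), mode = "joint",
                              record_topology = record_topology)
      net <- res_i$network
      res <- res_i
    }
    return(res)
  }

  ids <- link_ids(network)
  sig_ids <- paste(significance$from, significance$to, sep = "|")
  p <- significance$p_value[match(ids, sig_ids)]
  if (anyNA(p)) stop("every link needs a p-value; missing for ",
                     ids[which(is.na(p))[1]])
  for (ct in constraints) {
    miss <- setdiff(c(ct$set_a$members, ct$set_b$members), network$nodes)
    if (length(miss)) stop("anchor gene(s) absent from the network: ",
                           paste(miss, collapse = ", "))
  }

  ord <- order(-p, network$edges$weight, ids, method = "radix")
  g <- as_igraph(network)
  checker <- function(graph) {
    comp <- igraph::components(graph)$membership
    for (ct in constraints) {
      a <- ct$set_a$members; b <- ct$set_b$members
      if (length(intersect(a, b))) next
      if (!any(comp[a] %in% comp[b])) return(FALSE)
    }
    TRUE
  }

  L <- length(ord)
  tr_from <- character(L); tr_to <- character(L)
  tr_p <- numeric(L); tr_acc <- logical(L)
  topo_rows <- if (record_topology) vector("list", L + 1L) else NULL
  if (record_topology) topo_rows[[1]] <- topology_record(network, network)
  removed <- character()
  stop_link <- NA_character_
  stop_reason <- "links_exhausted"
  step <- 0L
  cur <- g
  for (l in ord) {
    eid <- igraph::get_edge_ids(cur, c(network$edges$from[l],
                                       network$edges$to[l]))
    candidate <- igraph::delete_edges(cur, eid)
    step <- step + 1L
    tr_from[step] <- network$edges$from[l]
    tr_to[step] <- network$edges$to[l]
    tr_p[step] <- p[l]
    if (checker(candidate)) {
      cur <- candidate
      removed <- c(removed, ids[l])
      tr_acc[step] <- TRUE
      if (record_topology) {
        topo_rows[[step + 1L]] <- topology_record(drop_links(network, removed),
                                                  network)
      }
    } else {
      tr_acc[step] <- FALSE
      stop_link <- ids[l]
      stop_reason <- "constraint_violated"
      break
    }
  }
  trace <- data.frame(step = seq_len(step), from = tr_from[seq_len(step)],
                      to = tr_to[seq_len(step)], p_value = tr_p[seq_len(step)],
                      accepted = tr_acc[seq_len(step)],
                      stringsAsFactors = FALSE)
  topo <- if (record_topology) {
    do.call(rbind, topo_rows[!vapply(topo_rows, is.null, logical(1))])
  } else NULL
  surviving <- drop_links(network, removed)
  structure(list(network = surviving, trace = trace, stop_link = stop_link,
                 topology = topo, stop_reason = stop_reason),
            class = "filter_result")
}

#' Plain weight-threshold filter (comparison baseline)
#'
#' Keeps the `n_keep` heaviest links (ties broken by canonical link id).
#' Unlike the significance-based filter this discards the low-weight
#' scales of the network entirely, which is what the backbone filter is
#' designed to avoid.
#'
#' @param network a [ppi_network()].
#' @param n_keep number of links to keep.
#' @return a [ppi_network()] with the same node set.
#' @export
weight_threshold_filter <- function(network, n_keep) {
  stopifnot(n_keep >= 0, n_keep <= nrow(network$edges))
  ord <- order(-network$edges$weight, link_ids(network), method = "radix")
  keep <- sort(ord[seq_len(n_keep)])
  ppi_network(network$nodes, network$edges[keep, , drop = FALSE])
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf(paste0("<filter_result> %d links removed, %d surviving; ",
                     "stop: %s (%s)\n"),
              sum(x$trace$accepted), nrow(x$network$edges),
              x$stop_reason,
              if (is.na(x$stop_link)) "-" else x$stop_link))
  invisible(x)
}

#' Write a filter result's artifacts
#'
#' @param result a [filter_network()] result.
#' @param dir output directory; writes `filtered_network.tsv`,
#'   `removal_trace.tsv` and (when recorded) `topology_series.tsv`.
#' @return named list of paths, invisibly.
#' @export
write_filter_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(network = file.path(dir, "filtered_network.tsv"),
                trace = file.path(dir, "removal_trace.tsv"))
  write_network(result$network, paths$network)
  tr <- result$trace
  tr$p_value <- sprintf("%.17g", tr$p_value)
  utils::write.table(tr, paths$trace, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(result$topology)) {
    paths$topology <- file.path(dir, "topology_series.tsv")
    tp <- result$topology
    for (col in names(tp)) tp[[col]] <- sprintf("%.17g", tp[[col]])
    utils::write.table(tp, paths$topology, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
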