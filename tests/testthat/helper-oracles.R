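# Independent oracles used across the suite: plain-R breadth-first
# search, combinatorial formulas and brute-force recomputations, kept
# deliberately naive and separate from the package's own code paths.

# random simple weighted network on n_nodes with integer weights
random_network <- function(n_nodes, n_links, seed, max_weight = 4L) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  pairs <- t(utils::combn(nodes, 2))
  idx <- sample(nrow(pairs), n_links)
  ppi_network(nodes, data.frame(from = pairs[idx, 1], to = pairs[idx, 2],
                                weight = sample(max_weight, n_links,
                                                replace = TRUE),
                                stringsAsFactors = FALSE))
}

oracle_adjacency <- function(network) {
  adj <- stats::setNames(vector("list", length(network$nodes)),
                         network$nodes)
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    adj[[e$from[i]]] <- c(adj[[e$from[i]]], e$to[i])
    adj[[e$to[i]]] <- c(adj[[e$to[i]]], e$from[i])
  }
  adj
}

# component labels by repeated BFS
oracle_components <- function(network) {
  adj <- oracle_adjacency(network)
  comp <- stats::setNames(integer(length(network$nodes)), network$nodes)
  cid <- 0L
  for (v in network$nodes) {
    if (comp[[v]] > 0L) next
    cid <- cid + 1L
    queue <- v
    comp[[v]] <- cid
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      for (w in adj[[u]]) {
        if (comp[[w]] == 0L) {
          comp[[w]] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

# hop distances from one source (Inf when unreachable)
oracle_bfs_dist <- function(adj, nodes, source) {
  d <- stats::setNames(rep(Inf, length(nodes)), nodes)
  d[[source]] <- 0
  queue <- source
  while (length(queue)) {
    u <- queue[1]
    queue <- queue[-1]
    for (w in adj[[u]]) {
      if (is.infinite(d[[w]])) {
        d[[w]] <- d[[u]] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

oracle_anchors_connected <- function(network, set_a, set_b) {
  comp <- oracle_components(network)
  any(comp[set_a] %in% comp[set_b])
}

# diameter, n_rel and mean isolated-component size by direct enumeration
oracle_topology <- function(network, original) {
  comp <- oracle_components(network)
  sizes <- table(comp)
  giant_id <- names(sizes)[which.max(sizes)]
  giant_nodes <- names(comp)[comp == as.integer(giant_id)]
  adj <- oracle_adjacency(network)
  diam <- 0
  if (length(giant_nodes) > 1) {
    for (v in giant_nodes) {
      d <- oracle_bfs_dist(adj, network$nodes, v)
      diam <- max(diam, max(d[giant_nodes]))
    }
  }
  others <- as.integer(sizes[names(sizes) != giant_id])
  list(diameter = diam,
       giant_relative_size = max(sizes) / length(original$nodes),
       mean_isolated_component_size = if (length(others)) mean(others) else 0)
}

# mean shortest-path length over connected ordered pairs
oracle_mean_path_length <- function(network) {
  net <- active_subnetwork(network)
  adj <- oracle_adjacency(net)
  total <- 0
  count <- 0
  for (v in net$nodes) {
    d <- oracle_bfs_dist(adj, net$nodes, v)
    d <- d[names(d) != v]
    total <- total + sum(d[is.finite(d)])
    count <- count + sum(is.finite(d))
  }
  if (count == 0) 0 else total / count
}

# mean local clustering coefficient, 0 for degree < 2
oracle_clustering <- function(network) {
  net <- active_subnetwork(network)
  adj <- lapply(oracle_adjacency(net), unique)
  cc <- vapply(net$nodes, function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2) return(0)
    m <- 0
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        if (nb[j] %in% adj[[nb[i]]]) m <- m + 1
      }
    }
    2 * m / (k * (k - 1))
  }, numeric(1))
  mean(cc)
}

# naive leave-one-out jackknife mean correlation via cor()
oracle_jackknife <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  mean(vapply(seq_along(x), function(i) stats::cor(x[-i], y[-i]),
              numeric(1)))
}

# upper-tail hypergeometric probability from the combinatorial formula
oracle_hypergeom <- function(N, K, n, k) {
  xs <- k:min(n, K)
  xs <- xs[n - xs <= N - K]
  if (!length(xs)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# the planted backbone-recovery scenario shared by several tests:
# 300 genes, 1500 links, a 20-link backbone, deep sampling
planted_scenario <- function(seed = 1L) {
  synthetic_scenario(n_genes = 300, n_samples = 200, n_links = 1500,
                     module_spec = list(c(30, 0.7), c(30, 0.5)),
                     backbone_length = 20, seed = seed)
}
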