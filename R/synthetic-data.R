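#' Define a synthetic study scenario
#'
#' A scenario bundles every parameter of the synthetic-data generators:
#' a sparse undirected interactome wired by preferential attachment, a
#' planted high-correlation backbone path joining three anchor gene sets
#' (a receptor-complex-like set and two downstream signalling sets), a
#' block-correlated expression matrix, and essentiality labels with
#' planted enrichment on the backbone.
#'
#' Correlation blocks are built from shared latent factors
#' (`sqrt(rho_out)` global factor + `sqrt(rho_in - rho_out)` module
#' factor + independent noise), which realises exactly the target block
#' correlation matrix and is positive semi-definite by construction;
#' configurations outside `0 <= rho_out <= min(rho_in) <= 1` are
#' rejected.
#'
#' @param n_genes number of genes (network nodes).
#' @param n_samples number of expression samples.
#' @param n_links number of network links (>= `backbone_length`,
#'   <= `choose(n_genes, 2)`).
#' @param module_spec list of `c(size, rho_in)` pairs for co-expression
#'   modules beyond the backbone module.
#' @param rho_out background correlation between genes in different
#'   modules.
#' @param backbone_rho within-module correlation of the backbone module.
#' @param anchor_sizes named integer vector `c(tcr=, nfkb=, nfat=)`:
#'   sizes of the three anchor gene sets.
#' @param backbone_length number of links on the planted backbone path.
#' @param backbone_weight_percentile percentile of the background weight
#'   distribution at which provisional backbone link weights start.
#' @param essential_fraction_overall probability that a non-backbone
#'   gene is labelled essential.
#' @param essential_fraction_backbone probability that a backbone gene
#'   is labelled essential.
#' @param missing_rate fraction of expression entries masked as missing,
#'   in `[0, 1)`.
#' @param seed integer master seed; the three generators draw from
#'   streams derived deterministically from it.
#' @return a list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_genes = 200, n_samples = 60, n_links = 800,
                               module_spec = list(c(25, 0.7), c(25, 0.5)),
                               rho_out = 0, backbone_rho = 0.9,
                               anchor_sizes = c(tcr = 4, nfkb = 4, nfat = 4),
                               backbone_length = 10,
                               backbone_weight_percentile = 0.9,
                               essential_fraction_overall = 0.15,
                               essential_fraction_backbone = 0.75,
                               missing_rate = 0.1, seed = 1L) {
  stopifnot(n_genes >= 4, n_samples >= 4, backbone_length >= 2,
            missing_rate >= 0, missing_rate < 1,
            essential_fraction_overall >= 0, essential_fraction_overall <= 1,
            essential_fraction_backbone >= 0, essential_fraction_backbone <= 1,
            backbone_weight_percentile >= 0, backbone_weight_percentile <= 1,
            all(c("tcr", "nfkb", "nfat") %in% names(anchor_sizes)))
  n_planted <- backbone_length +
    sum(pmax(anchor_sizes[c("tcr", "nfkb", "nfat")] - 1, 0))
  if (n_links > n_genes * (n_genes - 1) / 2 || n_links < n_planted) {
    stop("infeasible link count for this scenario")
  }
  rho_in <- vapply(module_spec, `[`, numeric(1), 2)
  if (any(abs(rho_in) > 1) || abs(rho_out) > 1 || abs(backbone_rho) > 1) {
    stop("correlations must lie in [-1, 1]")
  }
  if (rho_out < 0 || any(rho_in < rho_out) || backbone_rho < rho_out) {
    stop("block correlation matrix is not positive semi-definite under the ",
         "factor construction: need 0 <= rho_out <= every within-module rho")
  }
  sizes <- vapply(module_spec, `[`, numeric(1), 1)
  n_pathway <- backbone_length + 1 +
    sum(pmax(anchor_sizes[c("tcr", "nfkb", "nfat")] - 1, 0))
  if (sum(sizes) + n_pathway > n_genes) {
    stop("module sizes plus backbone exceed the number of genes")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_samples = as.integer(n_samples),
                 n_links = as.integer(n_links), module_spec = module_spec,
                 rho_out = rho_out, backbone_rho = backbone_rho,
                 anchor_sizes = anchor_sizes,
                 backbone_length = as.integer(backbone_length),
                 backbone_weight_percentile = backbone_weight_percentile,
                 essential_fraction_overall = essential_fraction_overall,
                 essential_fraction_backbone = essential_fraction_backbone,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

gene_names <- function(n) {
  sprintf("g%0*d", nchar(as.character(n)), seq_len(n))
}

#' Generate the synthetic interactome
#'
#' Wires a simple undirected graph: a preferential-attachment skeleton
#' (heavy-tailed degrees, as in real interactomes) plus a planted
#' backbone path routed through the skeleton's hubs -- in real
#' interactomes the core signalling proteins are hubs, and a
#' high-weight link is only statistically outstanding when it stands
#' out against many weaker links at its endpoints. The path visits one
#' representative of each anchor set in the order NF-kB-like
#' representative ... TCR-like representative ... NFAT-like
#' representative; the remaining anchor-set members attach to their
#' representative like complex subunits. Provisional link weights are
#' drawn from a right-skewed background distribution; planted links are
#' placed at or above the configured background percentile so tests can
#' run on the network without an expression matrix (the full pipeline
#' replaces all weights via [weigh_network()]).
#'
#' @param scenario a [synthetic_scenario()].
#' @return a [ppi_network()] with attributes `anchors` (named list of
#'   three [gene_set()]s), `backbone_nodes` (genes on the path) and
#'   `backbone_links` (canonical link ids of the planted path).
#' @export
generate_network <- function(scenario) {
  set.seed(scenario$seed)
  n <- scenario$n_genes
  genes <- sample(gene_names(n))  # random gene labels over node indices
  sz <- scenario$anchor_sizes
  n_members <- sum(pmax(sz[c("tcr", "nfkb", "nfat")] - 1, 0))

  # the terminal pathway representatives and the anchor-set members are
  # dedicated pathway genes: they touch the interactome only through the
  # planted pathway, so anchor-to-anchor connectivity genuinely depends
  # on the backbone
  n_dedicated <- 2L + n_members
  n_pa <- n - n_dedicated
  if (n_pa < max(scenario$backbone_length - 1L, 2L)) {
    stop("too few genes left for the interactome skeleton")
  }
  pa_genes <- genes[seq_len(n_pa)]
  dedicated <- genes[(n_pa + 1L):n]

  # preferential-attachment skeleton over the non-dedicated genes
  m <- max(1L, round(scenario$n_links / n))
  g <- igraph::sample_pa(n_pa, power = 1, m = min(m, n_pa - 1L),
                         directed = FALSE)
  deg <- igraph::degree(g)

  # backbone path: peripheral NF-kB-like representative, then the
  # skeleton's top hubs (core signalling proteins are interactome
  # hubs), then the peripheral NFAT-like representative; the TCR-like
  # representative is the middle hub
  n_interior <- scenario$backbone_length - 1L
  hub_order <- order(-deg, seq_len(n_pa))
  interior <- pa_genes[hub_order[seq_len(n_interior)]]
  rep_nfkb <- dedicated[1]
  rep_nfat <- dedicated[2]
  rep_tcr <- interior[ceiling(n_interior / 2)]
  bb_nodes <- c(rep_nfkb, interior, rep_nfat)
  bb_n <- length(bb_nodes)
  bb_edges <- data.frame(from = bb_nodes[-bb_n], to = bb_nodes[-1],
                         stringsAsFactors = FALSE)
  bb_ids <- paste(pmin(bb_edges$from, bb_edges$to),
                  pmax(bb_edges$from, bb_edges$to), sep = "|")

  members <- if (n_members > 0L) dedicated[2L + seq_len(n_members)] else character()
  i <- 0
  take <- function(k) {
    if (k <= 0) return(character())
    out <- members[(i + 1):(i + k)]; i <<- i + k; out
  }
  anchors <- list(
    tcr = gene_set("tcr", c(rep_tcr, take(sz[["tcr"]] - 1))),
    nfkb = gene_set("nfkb", c(rep_nfkb, take(sz[["nfkb"]] - 1))),
    nfat = gene_set("nfat", c(rep_nfat, take(sz[["nfat"]] - 1))))
  star <- function(set, rep) {
    mem <- setdiff(set$members, rep)
    if (!length(mem)) return(NULL)
    data.frame(from = rep, to = mem, stringsAsFactors = FALSE)
  }
  star_edges <- rbind(star(anchors$tcr, rep_tcr),
                      star(anchors$nfkb, rep_nfkb),
                      star(anchors$nfat, rep_nfat))
  planted <- rbind(bb_edges, star_edges)
  planted_ids <- paste(pmin(planted$from, planted$to),
                       pmax(planted$from, planted$to), sep = "|")

  el <- igraph::as_edgelist(g, names = FALSE)
  pa <- data.frame(from = pa_genes[el[, 1]], to = pa_genes[el[, 2]],
                   stringsAsFactors = FALSE)
  sw <- pa$from > pa$to
  tmp <- pa$from[sw]; pa$from[sw] <- pa$to[sw]; pa$to[sw] <- tmp
  pa_ids <- paste(pa$from, pa$to, sep = "|")
  keep <- !duplicated(pa_ids) & !(pa_ids %in% planted_ids) &
    pa$from != pa$to
  pa <- pa[keep, , drop = FALSE]
  pa_ids <- pa_ids[keep]

  n_bg <- scenario$n_links - length(planted_ids)
  if (nrow(pa) > n_bg) {
    pa <- pa[sort(sample(nrow(pa), n_bg)), , drop = FALSE]
  } else if (nrow(pa) < n_bg) {
    need <- n_bg - nrow(pa)
    existing <- c(planted_ids, pa_ids)
    add <- data.frame(from = character(), to = character())
    while (need > 0) {
      a <- sample(pa_genes, 2 * need, replace = TRUE)
      b <- sample(pa_genes, 2 * need, replace = TRUE)
      cand <- data.frame(from = pmin(a, b), to = pmax(a, b),
                         stringsAsFactors = FALSE)
      cand <- cand[cand$from != cand$to, , drop = FALSE]
      cid <- paste(cand$from, cand$to, sep = "|")
      ok <- !(cid %in% existing) & !duplicated(cid)
      cand <- cand[ok, , drop = FALSE][seq_len(min(need, sum(ok))), , drop = FALSE]
      existing <- c(existing, paste(cand$from, cand$to, sep = "|"))
      add <- rbind(add, cand)
      need <- n_bg - nrow(pa) - nrow(add)
    }
    pa <- rbind(pa, add)
  }

  w_bg <- stats::rbeta(nrow(pa), 2, 5)
  q <- if (nrow(pa) > 0) {
    stats::quantile(w_bg, scenario$backbone_weight_percentile)
  } else 0.8
  w_pl <- stats::runif(nrow(planted), min = q, max = 1)
  edges <- rbind(data.frame(pa, weight = w_bg, stringsAsFactors = FALSE),
                 data.frame(planted, weight = w_pl, stringsAsFactors = FALSE))
  net <- ppi_network(genes, edges)
  attr(net, "anchors") <- anchors
  attr(net, "backbone_nodes") <- bb_nodes
  attr(net, "backbone_links") <- sort(bb_ids)
  net
}

#' Generate a block-correlated expression matrix
#'
#' Draws `n_samples` multivariate-normal observations whose correlation
#' matrix has value `rho_in` within each configured module,
#' `backbone_rho^|i-j|` between backbone-path genes at path distance
#' `|i-j|` (a first-order autoregressive chain, emulating signal
#' propagation along a pathway), and `rho_out` elsewhere, then masks
#' entries completely at random at `missing_rate`.
#'
#' @param scenario a [synthetic_scenario()].
#' @param network the network from [generate_network()] (supplies the
#'   backbone gene module).
#' @return numeric matrix, genes in rows, samples in columns, `NA` for
#'   missing entries; attribute `modules` maps genes to module labels.
#' @export
generate_expression <- function(scenario, network) {
  set.seed(scenario$seed + 1L)
  genes <- network$nodes
  n_g <- length(genes)
  n_s <- scenario$n_samples

  module <- rep("background", n_g)
  names(module) <- genes
  rho <- rep(scenario$rho_out, n_g)
  # the pathway module: the backbone path genes (anchor-set members
  # interact with their representative but are not co-expressed with
  # the backbone module)
  bb <- attr(network, "backbone_nodes")
  module[bb] <- "backbone"
  rho[match(bb, genes)] <- scenario$backbone_rho
  pool <- setdiff(genes, bb)
  for (mi in seq_along(scenario$module_spec)) {
    sz <- scenario$module_spec[[mi]][1]
    members <- sample(pool, sz)
    pool <- setdiff(pool, members)
    module[members] <- paste0("module", mi)
    rho[match(members, genes)] <- scenario$module_spec[[mi]][2]
  }

  r_out <- scenario$rho_out
  z0 <- stats::rnorm(n_s)
  mods <- setdiff(unique(module), c("background", "backbone"))
  zmod <- matrix(stats::rnorm(max(length(mods), 1) * n_s),
                 nrow = max(length(mods), 1),
                 dimnames = list(if (length(mods)) mods else "none", NULL))
  eps <- matrix(stats::rnorm(n_g * n_s), nrow = n_g)
  x <- sqrt(r_out) * matrix(z0, n_g, n_s, byrow = TRUE)
  in_blk <- module %in% mods
  if (any(in_blk)) {
    x[in_blk, ] <- x[in_blk, , drop = FALSE] +
      sqrt(rho[in_blk] - r_out) * zmod[module[in_blk], , drop = FALSE]
  }
  load_eps <- ifelse(in_blk, sqrt(1 - rho), sqrt(1 - r_out))
  x <- x + load_eps * eps

  # the backbone is a signalling chain: correlation decays with path
  # distance as backbone_rho^|i-j| (first-order autoregressive process
  # along the path), so each path link joins the two most strongly
  # co-expressed neighbours
  bb_path <- attr(network, "backbone_nodes")
  r_bb <- scenario$backbone_rho
  if (length(bb_path) > 0) {
    ar <- matrix(0, length(bb_path), n_s)
    ar[1, ] <- stats::rnorm(n_s)
    for (j in seq_along(bb_path)[-1]) {
      ar[j, ] <- r_bb * ar[j - 1, ] + sqrt(1 - r_bb^2) * stats::rnorm(n_s)
    }
    rows <- match(bb_path, genes)
    x[rows, ] <- sqrt(r_out) * matrix(z0, length(bb_path), n_s, byrow = TRUE) +
      sqrt(1 - r_out) * ar
  }
  dimnames(x) <- list(genes, sprintf("s%0*d", nchar(as.character(n_s)),
                                     seq_len(n_s)))

  if (scenario$missing_rate > 0) {
    mask <- stats::runif(length(x)) < scenario$missing_rate
    x[mask] <- NA_real_
  }
  attr(x, "modules") <- module
  x
}

#' Per-gene non-missing sample fraction
#' @param expr expression matrix (genes x samples, `NA` = missing).
#' @return named numeric vector in `[0, 1]`.
#' @export
expressed_fraction <- function(expr) {
  rowMeans(!is.na(expr))
}

#' Generate essentiality annotations with planted backbone enrichment
#'
#' @param scenario a [synthetic_scenario()].
#' @param network the network from [generate_network()].
#' @return data.frame with columns `gene` and `is_essential` (0/1);
#'   backbone genes are essential with probability
#'   `essential_fraction_backbone`, all others with
#'   `essential_fraction_overall`.
#' @export
generate_annotations <- function(scenario, network) {
  set.seed(scenario$seed + 2L)
  genes <- network$nodes
  p <- rep(scenario$essential_fraction_overall, length(genes))
  p[genes %in% attr(network, "backbone_nodes")] <- scenario$essential_fraction_backbone
  data.frame(gene = genes,
             is_essential = as.integer(stats::runif(length(genes)) < p),
             stringsAsFactors = FALSE)
}

#' Materialise a scenario on disk
#'
#' Writes the edge list (TSV), expression matrix (TSV, missing cells
#' empty), the three anchor-set files, the annotation table and a
#' key-value manifest into a directory.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if absent).
#' @return named list of the file paths written, invisibly; the
#'   generated objects are returned in the `objects` element.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  net <- generate_network(scenario)
  expr <- generate_expression(scenario, net)
  ann <- generate_annotations(scenario, net)
  anchors <- attr(net, "anchors")

  paths <- list(edge_list = file.path(dir, "network.tsv"),
                expression = file.path(dir, "expression.tsv"),
                anchors_tcr = file.path(dir, "anchors_tcr.txt"),
                anchors_nfkb = file.path(dir, "anchors_nfkb.txt"),
                anchors_nfat = file.path(dir, "anchors_nfat.txt"),
                annotations = file.path(dir, "annotations.tsv"),
                backbone = file.path(dir, "backbone_links.txt"),
                manifest = file.path(dir, "scenario_manifest.txt"))
  write_network(net, paths$edge_list)
  write_expression(expr, paths$expression)
  write_gene_set(anchors$tcr, paths$anchors_tcr)
  write_gene_set(anchors$nfkb, paths$anchors_nfkb)
  write_gene_set(anchors$nfat, paths$anchors_nfat)
  utils::write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(attr(net, "backbone_links"), paths$backbone)
  scal <- scenario[!vapply(scenario, is.list, logical(1))]
  kv <- c(vapply(names(scal), function(k) {
    sprintf("%s: %s", k, paste(scal[[k]], collapse = ","))
  }, character(1)),
  sprintf("module_spec: %s", paste(vapply(scenario$module_spec, paste,
                                          character(1), collapse = ":"),
                                   collapse = ";")))
  writeLines(kv, paths$manifest)
  out <- paths
  out$objects <- list(network = net, expression = expr, annotations = ann,
                      anchors = anchors)
  invisible(out)
}

#' Write an expression matrix as TSV (missing cells empty)
#' @param expr genes x samples matrix with `NA` for missing.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  cells <- matrix(sprintf("%.17g", expr), nrow = nrow(expr))
  cells[is.na(expr)] <- ""
  df <- data.frame(gene = rownames(expr), cells,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("gene", colnames(expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression()]
#' @param path TSV path (first column gene id; empty cells = missing).
#' @return numeric matrix, genes in rows.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == ""] <- NA_character_
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}
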