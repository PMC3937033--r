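#' Empirical link-weight distribution on a discrete support
#'
#' Bins all link weights of the network at `bin_width` resolution (bin
#' index = `round(weight / bin_width)`, bin centers `index * bin_width`)
#' and normalises the counts to a probability distribution. With
#' correlation weights scaled by 100, the default unit bin gives
#' integer-resolution weights.
#'
#' @param network a [ppi_network()] with at least one link.
#' @param bin_width positive bin width (default 1).
#' @return list of class `weight_distribution`: `support` (bin centers,
#'   from 0), `prob` (probability per bin, sums to 1), `bin_width`,
#'   `index` (bin index of each network link, in link order).
#' @export
empirical_distribution <- function(network, bin_width = 1) {
  if (bin_width <= 0) stop("bin width must be positive")
  if (nrow(network$edges) == 0L) stop("network has no links")
  idx <- as.integer(round(network$edges$weight / bin_width))
  m <- max(idx)
  counts <- tabulate(idx + 1L, nbins = m + 1L)
  structure(list(support = (0:m) * bin_width,
                 prob = counts / sum(counts),
                 bin_width = bin_width, index = idx),
            class = "weight_distribution")
}

# m-fold self-convolutions of prob on the integer lattice: list where
# element m+1 is Q_m over indices 0..m*M; renormalised each step
self_convolutions <- function(prob, m_max) {
  out <- vector("list", m_max + 1L)
  out[[1]] <- 1  # Q_0: point mass at 0
  if (m_max >= 1L) out[[2]] <- prob
  if (m_max >= 2L) {
    for (m in 2:m_max) {
      prev <- out[[m]]
      q <- numeric(length(prev) + length(prob) - 1L)
      for (k in seq_along(prob)) {
        if (prob[k] > 0) {
          rng <- (k - 1L) + seq_along(prev)
          q[rng] <- q[rng] + prob[k] * prev
        }
      }
      out[[m + 1L]] <- q / sum(q)
    }
  }
  out
}

#' Per-link significance under the global weight-randomisation null
#'
#' The null model keeps the network topology fixed and assigns every
#' link a weight drawn independently from the network's empirical
#' weight distribution. The p-value of link (i, j) with observed weight
#' w is the probability that its null weight is at least w, conditioned
#' on both endpoint strengths:
#'
#'   p(w | s_i, s_j)  proportional to  P(w) Q_{k_i - 1}(s_i - w) Q_{k_j - 1}(s_j - w)
#'
#' where P is the empirical weight distribution, Q_m its m-fold
#' self-convolution (Q_0 a point mass at zero), k the endpoint degrees
#' and s the endpoint strengths, all at bin resolution. The two stars
#' around a link share only the link itself, so conditioning factorises
#' exactly. A degree-1 endpoint forces the null weight to equal the
#' observed one, giving p = 1: leaf links are maximally insignificant
#' by construction.
#'
#' @param network a [ppi_network()].
#' @param dist a [empirical_distribution()] of the same network (built
#'   with the desired bin width if omitted).
#' @param bin_width used when `dist` is missing.
#' @return data.frame of class `edge_significance`: `from`, `to`,
#'   `weight`, `k_i`, `k_j`, `s_i`, `s_j`, `p_value`, `flag` (normally
#'   `""`; `"unreachable_strength"` when the conditioning had to fall
#'   back to the nearest reachable strength bin).
#' @export
gloss_pvalues <- function(network, dist = NULL, bin_width = 1) {
  if (is.null(dist)) dist <- empirical_distribution(network, bin_width)
  e <- network$edges
  prob <- dist$prob
  m_sup <- length(prob) - 1L
  idx <- dist$index

  # binned strengths/degrees so conditioning is always attainable
  ns <- node_strengths(network)
  deg <- stats::setNames(ns$degree, ns$node)
  s_idx <- stats::setNames(numeric(nrow(ns)), ns$node)
  agg <- tapply(c(idx, idx), c(e$from, e$to), sum)
  s_idx[names(agg)] <- as.numeric(agg)

  q <- self_convolutions(prob, max(deg) - 1L)
  pval <- numeric(nrow(e))
  flag <- character(nrow(e))
  for (l in seq_len(nrow(e))) {
    ki <- deg[[e$from[l]]]; kj <- deg[[e$to[l]]]
    si <- s_idx[[e$from[l]]]; sj <- s_idx[[e$to[l]]]
    w_obs <- idx[l]
    qi <- q[[ki]]  # Q_{ki-1}
    qj <- q[[kj]]
    w_cand <- 0:m_sup
    # Q_m(s - w): valid lattice positions 0 .. m*M
    gi <- rest_mass(qi, si - w_cand)
    gj <- rest_mass(qj, sj - w_cand)
    g <- prob * gi * gj
    tot <- sum(g)
    if (tot <= 0) {
      # strength not reachable on the support (can only happen with a
      # foreign distribution); fall back to the nearest reachable bin
      flag[l] <- "unreachable_strength"
      si <- nearest_reachable(qi, prob, si)
      sj <- nearest_reachable(qj, prob, sj)
      g <- prob * rest_mass(qi, si - w_cand) * rest_mass(qj, sj - w_cand)
      tot <- sum(g)
    }
    pval[l] <- sum(g[w_cand >= w_obs]) / tot
  }
  out <- data.frame(from = e$from, to = e$to, weight = e$weight,
                    k_i = unname(deg[e$from]), k_j = unname(deg[e$to]),
                    s_i = unname(s_idx[e$from] * dist$bin_width),
                    s_j = unname(s_idx[e$to] * dist$bin_width),
                    p_value = pval, flag = flag, stringsAsFactors = FALSE)
  class(out) <- c("edge_significance", "data.frame")
  out
}

# Q evaluated at integer lattice points (0 outside its range)
rest_mass <- function(q, at) {
  out <- numeric(length(at))
  ok <- at >= 0 & at <= length(q) - 1L
  out[ok] <- q[at[ok] + 1L]
  out
}

# nearest strength index with positive conditional mass for some w
nearest_reachable <- function(q, prob, s) {
  m_sup <- length(prob) - 1L
  cand <- 0:(length(q) - 1L + m_sup)
  mass <- vapply(cand, function(sc) {
    sum(prob * rest_mass(q, sc - (0:m_sup)))
  }, numeric(1))
  ok <- cand[mass > 0]
  ok[which.min(abs(ok - s))]
}

#' Brute-force significance oracle (enumeration / Monte Carlo)
#'
#' Computes the same strength-conditioned tail probability as
#' [gloss_pvalues()] by enumerating every assignment of support weights
#' to every link (exhaustive mode), or by sampling assignments (Monte
#' Carlo mode), and conditioning on the two endpoint strengths at bin
#' resolution. Intended for validation on small networks only.
#'
#' @param network a [ppi_network()] (exhaustive mode: keep
#'   `support^links` manageable, e.g. <= 8 links with support <= 4).
#' @param dist a [empirical_distribution()].
#' @param n_draws number of Monte Carlo draws (`NULL` = exhaustive).
#' @param seed RNG seed for Monte Carlo mode.
#' @return data.frame `from`, `to`, `p_value`, `flag` (`"no_draws"`
#'   when no Monte Carlo draw matched the conditioning).
#' @export
null_oracle <- function(network, dist = NULL, n_draws = NULL, seed = 1L) {
  if (is.null(dist)) dist <- empirical_distribution(network)
  e <- network$edges
  L <- nrow(e)
  sup_idx <- which(dist$prob > 0) - 1L
  idx_obs <- dist$index
  nodes <- network$nodes
  inc <- lapply(nodes, function(v) which(e$from == v | e$to == v))
  names(inc) <- nodes
  s_obs <- vapply(nodes, function(v) sum(idx_obs[inc[[v]]]), numeric(1))

  if (is.null(n_draws)) {
    grid <- as.matrix(expand.grid(rep(list(sup_idx), L)))
    lp <- matrix(log(dist$prob[grid + 1L]), nrow = nrow(grid))
    w_assign <- exp(rowSums(lp))
  } else {
    set.seed(seed)
    grid <- matrix(sample(sup_idx, n_draws * L, replace = TRUE,
                          prob = dist$prob[sup_idx + 1L]),
                   nrow = n_draws)
    w_assign <- rep(1, n_draws)
  }

  pval <- numeric(L)
  flag <- character(L)
  for (l in seq_len(L)) {
    si <- rowSums(grid[, inc[[e$from[l]]], drop = FALSE])
    sj <- rowSums(grid[, inc[[e$to[l]]], drop = FALSE])
    cond <- si == s_obs[[e$from[l]]] & sj == s_obs[[e$to[l]]]
    denom <- sum(w_assign[cond])
    if (denom <= 0) {
      flag[l] <- "no_draws"
      pval[l] <- NA_real_
    } else {
      pval[l] <- sum(w_assign[cond & grid[, l] >= idx_obs[l]]) / denom
    }
  }
  data.frame(from = e$from, to = e$to, p_value = pval, flag = flag,
             stringsAsFactors = FALSE)
}

#' Write an edge-significance table as TSV
#' @param significance result of [gloss_pvalues()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_significance <- function(significance, path) {
  df <- significance
  for (col in c("weight", "s_i", "s_j", "p_value")) {
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
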