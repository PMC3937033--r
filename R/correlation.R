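#' Keep genes expressed in at least a given fraction of samples
#'
#' "Expressed" means non-missing: real presence calls are upstream of
#' the expression matrix this pipeline consumes, which only carries a
#' missingness mask. The boundary is inclusive (a gene present in
#' exactly `min_fraction` of samples is kept).
#'
#' @param expr genes x samples matrix, `NA` = missing.
#' @param min_fraction minimum non-missing fraction, in `(0, 1]`
#'   (default 0.8).
#' @return the filtered matrix, gene order preserved; attribute
#'   `n_dropped` records how many genes were removed.
#' @export
filter_expressed_genes <- function(expr, min_fraction = 0.8) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  frac <- expressed_fraction(expr)
  keep <- frac >= min_fraction
  if (!any(keep)) stop("no gene passes the expressed-fraction filter")
  out <- expr[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Mean jackknife Pearson correlation of two sample vectors
#'
#' Reduces `x` and `y` to pairwise-complete samples, then averages the
#' n leave-one-out Pearson correlations r_(-i). The estimator is the
#' plain mean of the leave-one-out coefficients, not the bias-corrected
#' pseudo-value form.
#'
#' @param x,y numeric vectors of equal length (`NA` allowed).
#' @return list with `mean_r` (in `[-1, 1]`) and `n_effective` (number
#'   of pairwise-complete samples).
#' @section Errors: fewer than 4 complete pairs raises an
#'   insufficient-data error (each leave-one-out subset needs at least
#'   3 points); zero variance in any leave-one-out subset raises an
#'   undefined-correlation error.
#' @export
jackknife_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("insufficient data: need >= 4 pairwise-complete samples")
  r <- jackknife_loo(x, y)
  if (anyNA(r)) stop("undefined correlation: zero variance in a leave-one-out subset")
  list(mean_r = mean(r), n_effective = n)
}

# leave-one-out Pearson correlations from running sums; NA where a
# subset has (numerically) zero variance
jackknife_loo <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  m <- n - 1
  num <- m * (sxy - x * y) - (sx - x) * (sy - y)
  vx <- m * (sxx - x^2) - (sx - x)^2
  vy <- m * (syy - y^2) - (sy - y)^2
  scale_x <- pmax(sxx, 1)
  scale_y <- pmax(syy, 1)
  bad <- vx <= 1e-12 * m^2 * scale_x | vy <= 1e-12 * m^2 * scale_y
  r <- ifelse(bad, NA_real_, num / sqrt(pmax(vx, 0) * pmax(vy, 0)))
  pmin(pmax(r, -1), 1)
}

#' Weigh network links by absolute mean jackknife correlation
#'
#' For every link whose two genes are present in the expression matrix,
#' computes the mean jackknife Pearson correlation and sets the link
#' weight to `scale * |mean_r|` (the conventional scale of 100 maps
#' correlations onto integer-resolution weights for the significance
#' step). Links with an endpoint missing from the matrix, or whose
#' correlation is undefined, are dropped and counted.
#'
#' @param network a [ppi_network()].
#' @param expr genes x samples expression matrix (typically already
#'   passed through [filter_expressed_genes()]).
#' @param scale multiplier applied to `|mean_r|` (default 100).
#' @return list with `network` (re-weighted [ppi_network()]), `weights`
#'   (data.frame: `from`, `to`, `mean_r`, `weight`, `scaled_weight`,
#'   `n_effective`) and `log` (counts `n_links_unexpressed`,
#'   `n_links_undefined`).
#' @export
weigh_network <- function(network, expr, scale = 100) {
  e <- network$edges
  present <- e$from %in% rownames(expr) & e$to %in% rownames(expr)
  n_unexpr <- sum(!present)
  e <- e[present, , drop = FALSE]
  mean_r <- rep(NA_real_, nrow(e))
  n_eff <- rep(NA_integer_, nrow(e))
  for (i in seq_len(nrow(e))) {
    res <- tryCatch(jackknife_correlation(expr[e$from[i], ], expr[e$to[i], ]),
                    error = function(err) NULL)
    if (!is.null(res)) {
      mean_r[i] <- res$mean_r
      n_eff[i] <- res$n_effective
    }
  }
  defined <- !is.na(mean_r)
  n_undef <- sum(!defined)
  e <- e[defined, , drop = FALSE]
  mean_r <- mean_r[defined]; n_eff <- n_eff[defined]
  weights <- data.frame(from = e$from, to = e$to, mean_r = mean_r,
                        weight = abs(mean_r),
                        scaled_weight = scale * abs(mean_r),
                        n_effective = n_eff, stringsAsFactors = FALSE)
  net <- ppi_network(network$nodes,
                     data.frame(from = e$from, to = e$to,
                                weight = scale * abs(mean_r),
                                stringsAsFactors = FALSE))
  for (a in c("anchors", "backbone_nodes", "backbone_links")) {
    if (!is.null(attr(network, a))) attr(net, a) <- attr(network, a)
  }
  list(network = net, weights = weights,
       log = list(n_links_unexpressed = n_unexpr,
                  n_links_undefined = n_undef))
}
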