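#' Hypergeometric over-representation test
#'
#' Tests whether an annotation (e.g. essential genes) is
#' over-represented in a sample of genes (e.g. the filtered network's
#' genes) drawn from a universe. Genes in the sample that are outside
#' the universe are dropped and counted. The p-value is the upper tail
#' of the hypergeometric distribution,
#' p = sum_{x = k}^{min(n, K)} C(K, x) C(N-K, n-x) / C(N, n),
#' identical to a one-sided Fisher's exact test on the corresponding
#' 2x2 table; a two-sided Fisher option is available.
#'
#' @param universe [gene_set()]: the background (size N).
#' @param annotated [gene_set()]: annotated genes; intersected with the
#'   universe (size K).
#' @param sample [gene_set()]: the genes tested for over-representation
#'   (size n after intersection with the universe; overlap with the
#'   annotation is k).
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"` (Fisher's exact test).
#' @return one-row data.frame of class `enrichment_result`: `N`, `K`,
#'   `n`, `k`, `expected` (= n K / N), `p_value`, `n_dropped` (sample
#'   genes outside the universe).
#' @export
hypergeom_enrichment <- function(universe, annotated, sample,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  u <- universe$members
  if (length(u) == 0L) stop("empty universe")
  s <- intersect(sample$members, u)
  n_dropped <- length(sample$members) - length(s)
  if (length(s) == 0L) stop("empty sample after intersection with the universe")
  a <- intersect(annotated$members, u)
  N <- length(u); K <- length(a); n <- length(s)
  k <- length(intersect(s, a))
  p <- if (alternative == "greater") {
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), nrow = 2)
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  }
  out <- data.frame(N = N, K = K, n = n, k = k, expected = n * K / N,
                    p_value = p, n_dropped = n_dropped)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; values are returned in the
#' input order, are monotone in the ranked p-values, never below the
#' raw p-value and capped at 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Select essential genes from phenotype annotation rows
#'
#' Keeps genes whose phenotype text contains the word "lethality"
#' (case-insensitive substring) and whose annotation-type text contains
#' neither "partial" nor "wean" -- i.e. complete, pre-weaning-excluded
#' lethality calls.
#'
#' @param annotations data.frame with columns `gene`, `phenotype`,
#'   `annotation_type`.
#' @return a [gene_set()] named `"essential"`.
#' @export
essential_gene_filter <- function(annotations) {
  stopifnot(all(c("gene", "phenotype", "annotation_type") %in%
                names(annotations)))
  keep <- grepl("lethality", annotations$phenotype, ignore.case = TRUE) &
    !grepl("partial", annotations$annotation_type, ignore.case = TRUE) &
    !grepl("wean", annotations$annotation_type, ignore.case = TRUE)
  gene_set("essential", annotations$gene[keep])
}

#' Essential-gene enrichment of a filtered network
#'
#' Convenience wrapper: tests over-representation of essential genes
#' among the genes that retain at least one link in the filtered
#' network, against a configurable universe (default: all genes of the
#' original network that carry an annotation).
#'
#' @param filtered surviving [ppi_network()] (isolated nodes ignored).
#' @param original the unfiltered [ppi_network()].
#' @param essential a [gene_set()] of essential genes (e.g. from
#'   [essential_gene_filter()] or a binary-label table).
#' @param universe optional [gene_set()] overriding the default
#'   background.
#' @return an `enrichment_result` (see [hypergeom_enrichment()]).
#' @export
essential_enrichment <- function(filtered, original, essential,
                                 universe = NULL) {
  if (is.null(universe)) universe <- gene_set("network", original$nodes)
  surviving <- unique(c(filtered$edges$from, filtered$edges$to))
  hypergeom_enrichment(universe, essential,
                       gene_set("filtered", surviving))
}
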