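#' Load an edge list and apply structural pre-filters
#'
#' Reads a tab-separated edge list (two identifier columns, optional
#' numeric weight column; header lines starting with `#` are skipped)
#' and applies the standard interactome clean-up: self-interactions are
#' omitted, multiple records for the same unordered gene pair are
#' collapsed to a single link, and, when a membership set is supplied,
#' links with either endpoint outside it are dropped.
#'
#' When duplicate records carry conflicting weights the first record
#' wins and the conflict is counted in the log.
#'
#' @param path TSV file path.
#' @param member_set optional [gene_set()]; links must have both
#'   endpoints inside it.
#' @return a [ppi_network()] with attribute `log`: a list with counts
#'   `n_records`, `n_self_loops`, `n_duplicates`, `n_weight_conflicts`,
#'   `n_nonmember`.
#' @export
load_edge_list <- function(path, member_set = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("edge list is empty; returning an empty network")
    net <- ppi_network(character())
    attr(net, "log") <- list(n_records = 0L, n_self_loops = 0L,
                             n_duplicates = 0L, n_weight_conflicts = 0L,
                             n_nonmember = 0L)
    return(net)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2L)
  if (length(bad)) {
    stop(sprintf("malformed edge-list row (need >= 2 tab-separated fields) at line %d",
                 bad[1]))
  }
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  if (any(!nzchar(from)) || any(!nzchar(to))) {
    stop(sprintf("empty gene identifier at line %d",
                 which(!nzchar(from) | !nzchar(to))[1]))
  }
  weight <- rep(1, length(from))
  has_w <- nf >= 3L
  if (any(has_w)) {
    wtxt <- rep(NA_character_, length(from))
    wtxt[has_w] <- vapply(parts[has_w], `[[`, character(1), 3L)
    w <- suppressWarnings(as.numeric(wtxt))
    if (any(has_w & is.na(w))) {
      stop(sprintf("non-numeric weight at line %d", which(has_w & is.na(w))[1]))
    }
    weight[has_w] <- w[has_w]
  }
  n_records <- length(from)

  self <- from == to
  n_self <- sum(self)
  from <- from[!self]; to <- to[!self]; weight <- weight[!self]

  n_nonmember <- 0L
  if (!is.null(member_set)) {
    ok <- from %in% member_set$members & to %in% member_set$members
    n_nonmember <- sum(!ok)
    from <- from[ok]; to <- to[ok]; weight <- weight[ok]
  }

  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  key <- paste(from, to, sep = "\r")
  first <- !duplicated(key)
  n_dup <- sum(!first)
  # conflicting weights among collapsed duplicates: first record kept
  n_conflict <- 0L
  if (n_dup > 0L) {
    w_first <- weight[first][match(key, key[first])]
    n_conflict <- length(unique(key[!first][weight[!first] != w_first[!first]]))
  }
  from <- from[first]; to <- to[first]; weight <- weight[first]

  if (length(from) == 0L) warning("all records filtered out; network has no links")
  net <- ppi_network(unique(c(from, to)),
                     data.frame(from = from, to = to, weight = weight,
                                stringsAsFactors = FALSE))
  attr(net, "log") <- list(n_records = n_records, n_self_loops = n_self,
                           n_duplicates = n_dup,
                           n_weight_conflicts = n_conflict,
                           n_nonmember = n_nonmember)
  net
}

#' Write a network to TSV or GraphML
#'
#' The TSV dialect writes `gene_a`, `gene_b`, `weight` (and `p_value`
#' when significance is supplied) with full double precision, so a
#' write/load round trip is lossless. GraphML goes through igraph and
#' carries the same link attributes.
#'
#' @param network a [ppi_network()].
#' @param path output file path.
#' @param p_values optional [gloss_pvalues()] table; matched to links by
#'   canonical id.
#' @param format `"tsv"` or `"graphml"` (default guessed from the file
#'   extension, falling back to TSV).
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, p_values = NULL, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "tsv"
  }
  format <- match.arg(format, c("tsv", "graphml"))
  pv <- NULL
  if (!is.null(p_values)) {
    ids <- link_ids(network)
    pid <- paste(p_values$from, p_values$to, sep = "|")
    pv <- p_values$p_value[match(ids, pid)]
  }
  if (format == "tsv") {
    df <- data.frame(gene_a = network$edges$from, gene_b = network$edges$to,
                     weight = sprintf("%.17g", network$edges$weight),
                     stringsAsFactors = FALSE)
    if (!is.null(pv)) df$p_value <- sprintf("%.17g", pv)
    # '#'-prefixed header so the file doubles as a plain edge list
    writeLines(paste0("#", paste(names(df), collapse = "\t")), path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, col.names = FALSE,
                                        append = TRUE))
  } else {
    g <- as_igraph(network)
    if (!is.null(pv)) igraph::E(g)$p_value <- pv
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path file path (TSV or GraphML, guessed from the extension).
#' @return a [ppi_network()]; a `p_value` column read from the file is
#'   attached as attribute `p_values`.
#' @export
read_network <- function(path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    g <- igraph::read_graph(path, format = "graphml")
    el <- igraph::as_edgelist(g, names = TRUE)
    w <- if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight else rep(1, nrow(el))
    net <- ppi_network(igraph::V(g)$name,
                       data.frame(from = el[, 1], to = el[, 2], weight = w,
                                  stringsAsFactors = FALSE))
    if ("p_value" %in% igraph::edge_attr_names(g)) {
      pid <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|")
      attr(net, "p_values") <- igraph::E(g)$p_value[match(link_ids(net), pid)]
    }
    return(net)
  }
  header <- sub("^#", "", readLines(path, n = 1))
  df <- utils::read.table(path, sep = "\t", skip = 1,
                          col.names = strsplit(header, "\t")[[1]],
                          colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L) return(ppi_network(character()))
  net <- ppi_network(unique(c(df$gene_a, df$gene_b)),
                     data.frame(from = df$gene_a, to = df$gene_b,
                                weight = as.numeric(df$weight),
                                stringsAsFactors = FALSE))
  if ("p_value" %in% names(df)) {
    pid <- paste(pmin(df$gene_a, df$gene_b), pmax(df$gene_a, df$gene_b), sep = "|")
    attr(net, "p_values") <- as.numeric(df$p_value)[match(link_ids(net), pid)]
  }
  net
}

#' Read a gene-set file (one identifier per line)
#'
#' @param path file path; blank lines and `#` comments are skipped.
#' @param name set label (default: file base name).
#' @return a [gene_set()].
#' @export
read_gene_set <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  gene_set(name, ids)
}

#' Write a gene set, one identifier per line
#' @param set a [gene_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(set, path) {
  writeLines(set$members, path)
  invisible(path)
}
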