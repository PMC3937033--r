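#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end run. Defaults mirror the
#' method's stated settings: expressed-gene threshold 0.8, correlation
#' scale 100, unit significance bins, joint anchor constraints, LWRN
#' fractions 0.1-0.9 with 30 iterations.
#'
#' @param scenario a [synthetic_scenario()] (used by the `simulate`
#'   stage; ignored when input paths point at existing files).
#' @param out_dir output directory for all artifacts.
#' @param min_expressed_fraction expressed-gene threshold.
#' @param weight_scale correlation-to-weight multiplier.
#' @param bin_width significance bin width.
#' @param constraint_mode `"joint"` or `"sequential"`.
#' @param lwrn_fractions,lwrn_iterations robustness experiment size
#'   (set `lwrn_iterations = 0` to skip the stage).
#' @param seed master seed for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = synthetic_scenario(),
                            out_dir = tempfile("tppin_run_"),
                            min_expressed_fraction = 0.8,
                            weight_scale = 100, bin_width = 1,
                            constraint_mode = "joint",
                            lwrn_fractions = seq(0.1, 0.9, by = 0.1),
                            lwrn_iterations = 30L, seed = NULL) {
  if (is.null(seed)) seed <- scenario$seed
  structure(list(scenario = scenario, out_dir = out_dir,
                 min_expressed_fraction = min_expressed_fraction,
                 weight_scale = weight_scale, bin_width = bin_width,
                 constraint_mode = constraint_mode,
                 lwrn_fractions = lwrn_fractions,
                 lwrn_iterations = as.integer(lwrn_iterations),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full backbone-extraction pipeline on a synthetic scenario
#'
#' Chains the stages: simulate (write the scenario's files), build
#' (reload the edge list through the structural pre-filters), correlate
#' (expressed-gene filter + jackknife link weighting), significance
#' (global-null p-values), filter (connectivity-constrained descending
#' p-value removal with topology monitoring), robustness (reduced LWRN
#' experiment, optional) and enrich (essential genes and planted
#' backbone links in the surviving network). Every artifact is written
#' under `config$out_dir` together with a run manifest, and all numeric
#' output is byte-reproducible given the same seed.
#'
#' @param config a [pipeline_config()].
#' @param stages character vector of stages to run (default all).
#' @return list with the in-memory results of each stage, invisibly:
#'   `scenario_files`, `network`, `weighted`, `significance`, `filter`,
#'   `lwrn`, `enrichment`, `log`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "build", "correlate",
                                    "significance", "filter", "robustness",
                                    "enrich")) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  out <- list()

  sim <- write_scenario(config$scenario, file.path(config$out_dir, "input"))
  out$scenario_files <- sim[names(sim) != "objects"]
  anchors <- sim$objects$anchors
  backbone_links <- attr(sim$objects$network, "backbone_links")

  net <- load_edge_list(sim$edge_list)
  attr(net, "anchors") <- anchors
  attr(net, "backbone_links") <- backbone_links
  attr(net, "backbone_nodes") <- attr(sim$objects$network, "backbone_nodes")
  log$build <- attr(net, "log")
  out$network <- net
  if (!("correlate" %in% stages)) return(invisible(c(out, list(log = log))))

  expr <- read_expression(sim$expression)
  expr <- filter_expressed_genes(expr, config$min_expressed_fraction)
  log$n_genes_dropped_expression <- attr(expr, "n_dropped")
  weighted <- weigh_network(net, expr, scale = config$weight_scale)
  log$correlate <- weighted$log
  utils::write.table(
    transform(weighted$weights,
              mean_r = sprintf("%.17g", mean_r),
              weight = sprintf("%.17g", weight),
              scaled_weight = sprintf("%.17g", scaled_weight)),
    file.path(config$out_dir, "weight_table.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  out$weighted <- weighted
  if (!("significance" %in% stages)) return(invisible(c(out, list(log = log))))

  sig <- gloss_pvalues(weighted$network, bin_width = config$bin_width)
  write_significance(sig, file.path(config$out_dir, "edge_significance.tsv"))
  out$significance <- sig
  if (!("filter" %in% stages)) return(invisible(c(out, list(log = log))))

  constraints <- list(anchor_constraint(anchors$tcr, anchors$nfkb),
                      anchor_constraint(anchors$tcr, anchors$nfat))
  res <- filter_network(weighted$network, sig, constraints,
                        mode = config$constraint_mode)
  write_filter_result(res, config$out_dir)
  log$n_links_removed <- sum(res$trace$accepted)
  log$stop_reason <- res$stop_reason
  out$filter <- res

  if ("robustness" %in% stages && config$lwrn_iterations > 0L) {
    lwrn <- lwrn_experiment(weighted$network, res, constraints,
                            fractions = config$lwrn_fractions,
                            iterations = config$lwrn_iterations,
                            seed = config$seed, bin_width = config$bin_width)
    write_lwrn_report(lwrn, file.path(config$out_dir, "lwrn_report.tsv"))
    out$lwrn <- lwrn
  }

  if ("enrich" %in% stages) {
    ann <- sim$objects$annotations
    essential <- gene_set("essential", ann$gene[ann$is_essential == 1])
    enr_genes <- essential_enrichment(res$network, weighted$network, essential)
    all_ids <- link_ids(weighted$network)
    enr_backbone <- hypergeom_enrichment(
      gene_set("links", all_ids),
      gene_set("backbone", intersect(backbone_links, all_ids)),
      gene_set("surviving", link_ids(res$network)))
    enr <- rbind(cbind(test = "essential_genes", enr_genes),
                 cbind(test = "backbone_links", enr_backbone))
    enr$p_adjusted <- bh_adjust(enr$p_value)
    utils::write.table(
      transform(enr, expected = sprintf("%.17g", expected),
                p_value = sprintf("%.17g", p_value),
                p_adjusted = sprintf("%.17g", p_adjusted)),
      file.path(config$out_dir, "enrichment.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    out$enrichment <- enr
  }

  write_manifest(config, log, file.path(config$out_dir, "run_manifest.txt"))
  out$log <- log
  invisible(out)
}

write_manifest <- function(config, log, path) {
  flat <- function(x, prefix = "") {
    out <- character()
    for (k in names(x)) {
      v <- x[[k]]
      if (is.list(v) && !is.null(names(v))) {
        out <- c(out, flat(v, paste0(prefix, k, ".")))
      } else if (inherits(v, "synthetic_scenario")) {
        out <- c(out, flat(unclass(v)[!vapply(v, is.list, logical(1))],
                           paste0(prefix, k, ".")))
      } else {
        out <- c(out, sprintf("%s%s: %s", prefix, k,
                              paste(unlist(v), collapse = ",")))
      }
    }
    out
  }
  writeLines(c(flat(config[names(config) != "scenario"]),
               flat(list(scenario = config$scenario)),
               flat(log)), path)
  invisible(path)
}
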