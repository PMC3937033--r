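test_that("scenario validation rejects infeasible parameters", {
  expect_error(synthetic_scenario(n_genes = 10, n_links = 100),
               "infeasible link count")
  expect_error(synthetic_scenario(n_links = 5, backbone_length = 10),
               "infeasible link count")
  expect_error(synthetic_scenario(rho_out = 0.8,
                                  module_spec = list(c(20, 0.5))),
               "positive semi-definite")
  expect_error(synthetic_scenario(module_spec = list(c(20, 1.5))),
               "\\[-1, 1\\]")
  expect_error(synthetic_scenario(n_genes = 40, n_links = 100,
                                  module_spec = list(c(35, 0.5))),
               "exceed")
})

test_that("generated network is simple, has the requested size and a connected backbone", {
  sc <- synthetic_scenario(n_genes = 10, n_samples = 10, n_links = 9,
                           module_spec = list(), anchor_sizes = c(tcr = 1, nfkb = 1, nfat = 1),
                           backbone_length = 3, seed = 5)
  net <- generate_network(sc)
  expect_equal(length(net$nodes), 10)
  expect_equal(n_links(net), 9)
  expect_true(all(net$edges$from < net$edges$to))
  expect_false(anyDuplicated(link_ids(net)) > 0)

  # larger wiring: anchors pairwise connected, by the BFS oracle
  sc2 <- synthetic_scenario(n_genes = 300, n_samples = 10, n_links = 1500,
                            seed = 1)
  net2 <- generate_network(sc2)
  expect_equal(n_links(net2), 1500)
  an <- attr(net2, "anchors")
  expect_true(oracle_anchors_connected(net2, an$tcr$members, an$nfkb$members))
  expect_true(oracle_anchors_connected(net2, an$tcr$members, an$nfat$members))
  expect_true(oracle_anchors_connected(net2, an$nfkb$members, an$nfat$members))

  # planted backbone links exist in the network
  expect_true(all(attr(net2, "backbone_links") %in% link_ids(net2)))
})

test_that("generators are deterministic under a fixed seed", {
  sc <- synthetic_scenario(n_genes = 50, n_samples = 20, n_links = 120,
                           module_spec = list(c(10, 0.6)), seed = 11)
  n1 <- generate_network(sc)
  n2 <- generate_network(sc)
  expect_identical(n1$edges, n2$edges)
  expect_identical(attr(n1, "anchors"), attr(n2, "anchors"))
  e1 <- generate_expression(sc, n1)
  e2 <- generate_expression(sc, n2)
  expect_identical(e1, e2)
  a1 <- generate_annotations(sc, n1)
  expect_identical(a1, generate_annotations(sc, n2))
})

test_that("expression matrix realises the planted correlation structure", {
  # degenerate block: rho 1, no noise -> sample correlation exactly 1
  sc <- synthetic_scenario(n_genes = 10, n_samples = 20, n_links = 9,
                           module_spec = list(c(2, 1.0)), backbone_rho = 1,
                           anchor_sizes = c(tcr = 1, nfkb = 1, nfat = 1),
                           missing_rate = 0, backbone_length = 3, seed = 2)
  net <- generate_network(sc)
  expr <- generate_expression(sc, net)
  mod <- attr(expr, "modules")
  pair <- names(mod)[mod == "module1"]
  expect_equal(stats::cor(expr[pair[1], ], expr[pair[2], ]), 1,
               tolerance = 1e-12)

  # independent background: mean |cross correlation| small at n = 500
  sc0 <- synthetic_scenario(n_genes = 40, n_samples = 500, n_links = 60,
                            module_spec = list(), rho_out = 0,
                            missing_rate = 0, backbone_length = 3, seed = 3)
  net0 <- generate_network(sc0)
  ex0 <- generate_expression(sc0, net0)
  bg <- names(attr(ex0, "modules"))[attr(ex0, "modules") == "background"]
  cm <- stats::cor(t(ex0[bg, ]))
  expect_lt(mean(abs(cm[upper.tri(cm)])), 0.1)

  # within-module correlation converges to rho_in (tolerance 3/sqrt(n))
  sc7 <- synthetic_scenario(n_genes = 60, n_samples = 400, n_links = 100,
                            module_spec = list(c(15, 0.7)), missing_rate = 0,
                            seed = 4)
  net7 <- generate_network(sc7)
  ex7 <- generate_expression(sc7, net7)
  m7 <- names(attr(ex7, "modules"))[attr(ex7, "modules") == "module1"]
  cm7 <- stats::cor(t(ex7[m7, ]))
  expect_lt(abs(mean(cm7[upper.tri(cm7)]) - 0.7), 3 / sqrt(400))
})

test_that("missingness is inserted at the requested rate", {
  sc <- synthetic_scenario(n_genes = 100, n_samples = 50, n_links = 300,
                           missing_rate = 0.2, seed = 6)
  net <- generate_network(sc)
  expr <- generate_expression(sc, net)
  expect_lt(abs(mean(is.na(expr)) - 0.2), 0.02)
  expect_equal(expressed_fraction(expr), rowMeans(!is.na(expr)))
})

test_that("annotations honour the planted essentiality fractions", {
  sc0 <- synthetic_scenario(essential_fraction_overall = 0,
                            essential_fraction_backbone = 0, seed = 8)
  net <- generate_network(sc0)
  expect_equal(sum(generate_annotations(sc0, net)$is_essential), 0)

  sc1 <- synthetic_scenario(essential_fraction_overall = 1,
                            essential_fraction_backbone = 1, seed = 8)
  net1 <- generate_network(sc1)
  ann1 <- generate_annotations(sc1, net1)
  expect_equal(sum(ann1$is_essential), nrow(ann1))

  # planted enrichment is detectable by the enrichment module
  sc <- synthetic_scenario(n_genes = 300, n_samples = 10, n_links = 900,
                           backbone_length = 20,
                           essential_fraction_overall = 0.2,
                           essential_fraction_backbone = 0.8, seed = 9)
  netp <- generate_network(sc)
  ann <- generate_annotations(sc, netp)
  res <- hypergeom_enrichment(
    gene_set("all", ann$gene),
    gene_set("ess", ann$gene[ann$is_essential == 1]),
    gene_set("backbone", attr(netp, "backbone_nodes")))
  expect_lt(res$p_value, 0.01)
})

test_that("scenario files round-trip through the readers", {
  sc <- synthetic_scenario(n_genes = 30, n_samples = 12, n_links = 60,
                           module_spec = list(c(6, 0.6)),
                           backbone_length = 4, seed = 10)
  dir <- withr::local_tempdir()
  files <- write_scenario(sc, dir)
  net <- load_edge_list(files$edge_list)
  expect_identical(net$edges[, c("from", "to")],
                   files$objects$network$edges[, c("from", "to")])
  expect_equal(net$edges$weight, files$objects$network$edges$weight,
               tolerance = 1e-15)
  expr <- read_expression(files$expression)
  expect_equal(expr, files$objects$expression, tolerance = 1e-15,
               ignore_attr = TRUE)
  tcr <- read_gene_set(files$anchors_tcr)
  expect_identical(tcr$members, files$objects$anchors$tcr$members)
  expect_true(file.exists(files$manifest))
})
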