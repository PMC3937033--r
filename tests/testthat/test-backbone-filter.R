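test_that("anchor connectivity matches a BFS oracle", {
  path <- ppi_network(c("A", "B", "C"),
                      data.frame(from = c("A", "B"), to = c("B", "C")))
  expect_true(anchors_connected(path, anchor_constraint(gene_set("a", "A"),
                                                        gene_set("b", "C"))))
  two <- ppi_network(c("A", "B", "C"),
                     data.frame(from = "A", to = "B"))
  expect_false(anchors_connected(two, anchor_constraint(gene_set("a", "A"),
                                                        gene_set("b", "C"))))
  expect_error(anchors_connected(two, anchor_constraint(gene_set("a", "A"),
                                                        gene_set("b", "Z"))),
               "absent")

  for (seed in 1:10) {
    net <- random_network(100, sample(80:200, 1), seed = seed)
    a <- sample(net$nodes, 3)
    b <- sample(net$nodes, 3)
    got <- anchors_connected(net, anchor_constraint(gene_set("a", a),
                                                    gene_set("b", b)))
    expect_identical(got, oracle_anchors_connected(net, a, b) ||
                       length(intersect(a, b)) > 0)
  }
})

test_that("topology records match brute-force component oracles", {
  # connected 4-path: diameter 3, n_rel 1, <s> 0
  p4 <- ppi_network(c("a", "b", "c", "d"),
                    data.frame(from = c("a", "b", "c"), to = c("b", "c", "d")))
  r <- topology_record(p4)
  expect_equal(r$diameter, 3)
  expect_equal(r$giant_relative_size, 1)
  expect_equal(r$mean_isolated_component_size, 0)

  # {4-path, 2-path} components: diameter 3, n_rel 4/6, <s> 2
  mix <- ppi_network(letters[1:6],
                     data.frame(from = c("a", "b", "c", "e"),
                                to = c("b", "c", "d", "f")))
  r2 <- topology_record(mix)
  expect_equal(r2$diameter, 3)
  expect_equal(r2$giant_relative_size, 4 / 6)
  expect_equal(r2$mean_isolated_component_size, 2)

  # 5-node star: diameter 2
  star <- ppi_network(c("h", "s1", "s2", "s3", "s4"),
                      data.frame(from = rep("h", 4),
                                 to = c("s1", "s2", "s3", "s4")))
  expect_equal(topology_record(star)$diameter, 2)

  # empty network: all-zero record
  r0 <- topology_record(ppi_network(character()))
  expect_true(all(unlist(r0) == 0))

  # random graphs against the oracle
  for (seed in 1:15) {
    net <- random_network(sample(10:50, 1), sample(8:60, 1), seed = seed + 30)
    got <- topology_record(net)
    want <- oracle_topology(net, net)
    expect_equal(got$diameter, want$diameter)
    expect_equal(got$giant_relative_size, want$giant_relative_size)
    expect_equal(got$mean_isolated_component_size,
                 want$mean_isolated_component_size)
  }
})

make_sig <- function(net, p) {
  data.frame(from = net$edges$from, to = net$edges$to, p_value = p,
             stringsAsFactors = FALSE)
}

test_that("the worked 4-node filtering example removes AB then stops at CD", {
  net <- ppi_network(c("A", "B", "C", "D"),
                     data.frame(from = c("A", "C", "B", "A"),
                                to = c("B", "D", "C", "C")))
  sig <- make_sig(net, c(0.9, 0.7, 0.5, 0.3)[match(link_ids(net),
                                                   c("A|B", "C|D", "B|C", "A|C"))])
  res <- filter_network(net, sig,
                        anchor_constraint(gene_set("a", "A"),
                                          gene_set("d", "D")))
  acc <- res$trace[res$trace$accepted, ]
  expect_equal(paste(acc$from, acc$to, sep = "|"), "A|B")
  expect_equal(res$stop_link, "C|D")
  expect_equal(res$stop_reason, "constraint_violated")
  expect_setequal(link_ids(res$network), c("B|C", "C|D", "A|C"))
})

test_that("a bridging link with the largest p-value stops filtering immediately", {
  net <- ppi_network(c("A", "B", "C"),
                     data.frame(from = c("A", "B"), to = c("B", "C")))
  sig <- make_sig(net, c(0.9, 0.1))
  res <- filter_network(net, sig,
                        anchor_constraint(gene_set("a", "A"),
                                          gene_set("b", "B")))
  expect_equal(sum(res$trace$accepted), 0)
  expect_equal(res$stop_link, "A|B")
  expect_identical(res$network$edges, net$edges)
})

test_that("filtering honours its contract on random networks", {
  for (seed in 1:12) {
    net <- random_network(30, sample(25:60, 1), seed = seed + 200)
    set.seed(seed)
    sig <- make_sig(net, stats::runif(n_links(net)))
    a <- sample(net$nodes, 2)
    b <- sample(setdiff(net$nodes, a), 2)
    ct <- anchor_constraint(gene_set("a", a), gene_set("b", b))
    res <- filter_network(net, sig, ct)

    # trace p-values non-increasing
    expect_true(all(diff(res$trace$p_value) <= 1e-12))
    # surviving network is a subset of the input
    expect_true(all(link_ids(res$network) %in% link_ids(net)))
    expect_identical(res$network$nodes, net$nodes)
    # replay: anchors connected after every accepted removal (oracle)
    acc <- res$trace[res$trace$accepted, ]
    if (nrow(acc) > 0 && oracle_anchors_connected(net, a, b)) {
      removed <- character()
      for (i in seq_len(nrow(acc))) {
        removed <- c(removed, paste(acc$from[i], acc$to[i], sep = "|"))
        expect_true(oracle_anchors_connected(drop_links(net, removed), a, b))
      }
    }
    # restored stop link is present in the surviving network
    if (!is.na(res$stop_link)) {
      expect_true(res$stop_link %in% link_ids(res$network))
    }
    # giant component never grows over the trace
    if (!is.null(res$topology)) {
      expect_true(all(diff(res$topology$giant_relative_size) <= 1e-12))
    }
    # idempotent safety: re-filtering the output never violates constraints
    sig2 <- sig[paste(sig$from, sig$to, sep = "|") %in%
                  link_ids(res$network), ]
    res2 <- filter_network(res$network, sig2, ct)
    expect_true(anchors_connected(res2$network, ct) ||
                  !oracle_anchors_connected(net, a, b))
  }
})

test_that("tie-breaking on equal p-values is deterministic", {
  net <- random_network(12, 20, seed = 77)
  sig <- make_sig(net, rep(0.5, 20))
  ct <- anchor_constraint(gene_set("a", net$nodes[1]),
                          gene_set("b", net$nodes[2]))
  r1 <- filter_network(net, sig, ct)
  r2 <- filter_network(net, sig, ct)
  expect_identical(r1$trace, r2$trace)
  # equal p: removal order is ascending weight, then lexicographic id
  acc <- r1$trace[r1$trace$accepted, ]
  w <- net$edges$weight[match(paste(acc$from, acc$to, sep = "|"),
                              link_ids(net))]
  expect_true(all(diff(w) >= 0))
})

test_that("sequential mode applies constraints one after another", {
  sc <- synthetic_scenario(n_genes = 40, n_samples = 10, n_links = 100,
                           module_spec = list(), backbone_length = 6, seed = 13)
  net <- generate_network(sc)
  an <- attr(net, "anchors")
  sig <- gloss_pvalues(net)
  cons <- list(anchor_constraint(an$tcr, an$nfkb),
               anchor_constraint(an$tcr, an$nfat))
  # pass 1 enforces the first constraint only; pass 2 then enforces the
  # second on pass 1's output, so only the last constraint is guaranteed
  # in the final network
  res1 <- filter_network(net, sig, cons[1], mode = "joint")
  expect_true(anchors_connected(res1$network, cons[[1]]))
  seq_res <- filter_network(net, sig, cons, mode = "sequential")
  expect_true(anchors_connected(seq_res$network, cons[[2]]))
  expect_true(all(link_ids(seq_res$network) %in% link_ids(res1$network)))
  # joint mode guarantees both throughout
  joint <- filter_network(net, sig, cons, mode = "joint")
  expect_true(anchors_connected(joint$network, cons[[1]]))
  expect_true(anchors_connected(joint$network, cons[[2]]))
})

test_that("filter artifacts are written and the threshold baseline works", {
  net <- random_network(15, 30, seed = 9)
  sig <- gloss_pvalues(net)
  ct <- anchor_constraint(gene_set("a", net$nodes[1]),
                          gene_set("b", net$nodes[15]))
  res <- filter_network(net, sig, ct)
  dir <- withr::local_tempdir()
  paths <- write_filter_result(res, dir)
  expect_true(all(file.exists(unlist(paths))))
  trace <- utils::read.table(paths$trace, sep = "\t", header = TRUE)
  expect_equal(nrow(trace), nrow(res$trace))

  thr <- weight_threshold_filter(net, 10)
  expect_equal(n_links(thr), 10)
  expect_gte(min(thr$edges$weight),
             max(net$edges$weight[!(link_ids(net) %in% link_ids(thr))]) - 1e-12)
})
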