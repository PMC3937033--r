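# tppin: core PPI network extraction by global link significance

`tppin` extracts the condition-relevant core of a weighted, undirected
protein–protein interaction network — the kind of analysis used to
distill a T cell-specific interaction network (a "TPPIN") out of a
large immune interactome, with the T cell receptor complex and its
NF-κB and NFAT signalling branches as connectivity anchors. It is aimed
at computational biologists who have an edge list, an expression
matrix, and a pair of landmark gene sets, and want the statistically
supported backbone of the network rather than an arbitrary weight
cutoff.

## The method

1. **Weights.** Each interacting gene pair gets weight
   `w = 100 · |mean jackknife Pearson r|`, the mean of the n
   leave-one-out correlations over pairwise-complete samples; genes
   present in < 80% of samples are dropped first.
2. **Significance.** Each link gets a p-value under a global null that
   fixes the topology and redraws all weights i.i.d. from the
   network's empirical weight distribution `P(w)`, conditioned on both
   endpoint strengths:
   `p(w | s_i, s_j) ∝ P(w) · Q_{k_i−1}(s_i − w) · Q_{k_j−1}(s_j − w)`,
   with `Q_m` the m-fold self-convolution of `P`;
   `p_e = Pr(W_e ≥ w_e | S_i = s_i, S_j = s_j)`. Links that dominate
   both endpoints are significant regardless of absolute weight, which
   is what preserves the network's multiscale structure.
3. **Filtering.** Links are removed in descending p-value order while
   at least one path survives between each anchor-set pair; the first
   removal that breaks a constraint is restored and filtering stops.
   Diameter, relative giant-component size `n_rel = n/N` and mean
   isolated-component size `⟨s⟩` are tracked at every step.
4. **Robustness.** Link-weight-randomized networks (a fraction of
   weights permuted, topology fixed) are re-filtered and compared to
   the reference core.
5. **Enrichment.** Upper-tail hypergeometric over-representation
   (≡ one-sided Fisher) of essential genes or planted backbone links
   in the surviving network, with Benjamini–Hochberg correction.

A synthetic-data module generates interactomes, block-correlated
expression matrices, anchor sets joined by a planted high-correlation
backbone, and essentiality labels, so the whole pipeline runs and is
tested end to end without external data.

## Worked example

```r
library(tppin)

sc  <- synthetic_scenario(seed = 1)          # 200 genes, 60 samples, 800 links
cfg <- pipeline_config(sc, out_dir = "demo_run",
                       lwrn_fractions = c(0.1, 0.5, 0.9), lwrn_iterations = 5)
res <- run_pipeline(cfg)

res$network
#> <ppi_network> 200 nodes, 800 links
res$filter
#> <filter_result> 602 links removed, 178 surviving; stop: constraint_violated (g004|g162)
res$filter$topology[nrow(res$filter$topology), ]
#>     links_removed_fraction nodes_isolated_fraction diameter giant_relative_size mean_isolated_component_size
#> 603              0.7717949                    0.16       16               0.685                     1.615385
res$enrichment[, c("test", "N", "K", "n", "k", "expected", "p_value")]
#>              test   N  K   n  k  expected      p_value
#> 1 essential_genes 200 29 168 24 24.360000 6.931646e-01
#> 2  backbone_links 780 10 178 10  2.282051 3.137699e-07
```

Reading the output: of the 800 simulated links, 780 survive expression
weighting (20 genes fail the 80% presence filter or have undefined
correlations); the constrained filter removes 602 links (77%) before a
removal would disconnect the anchor sets, and the restored stop link is
`g004|g162`. The surviving 178-link core still spans 68.5% of the nodes
in one component. All 10 planted backbone links are retained —
hypergeometric p ≈ 3×10⁻⁷ against a 2.3-link expectation — while
essential genes show no enrichment here because at this shallow
filtering depth 168 of 200 genes still carry a link.

The statistical primitives are exported individually
(`jackknife_correlation()`, `gloss_pvalues()`, `filter_network()`,
`lwrn_experiment()`, `hypergeom_enrichment()`, ...), e.g.:

```r
jackknife_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
#> $mean_r
#> [1] 0.7142857
#> $n_effective
#> [1] 4
```

A thin command-line wrapper over `run_pipeline()` is included at
`inst/cli/tppin-pipeline.R`.

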