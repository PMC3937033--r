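---
title: "Extracting the core of a weighted PPI network: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting the core of a weighted PPI network: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Protein–protein interaction (PPI) networks assembled from interaction
databases are noisy: many reported interactions are condition- or
tissue-irrelevant. `tppin` extracts the condition-relevant core of such
a network — the subnetwork supported by co-expression in a cell type of
interest (the motivating case is T cells, with the T cell receptor
complex and its NF-κB and NFAT downstream branches as landmark
pathways) — without discarding the network's multiscale weight
structure the way a simple weight threshold would.

The pipeline has five stages:

1. **Link weighting.** Each interacting gene pair is weighted by the
   absolute mean jackknife Pearson correlation of its expression
   profiles, multiplied by 100.
2. **Link significance.** Each link gets a p-value under a global null
   model: topology fixed, all link weights redrawn independently from
   the network's empirical weight distribution.
3. **Constrained filtering.** Links are deleted in descending p-value
   order while at least one path persists between designated anchor
   gene sets; the first removal that would break a constraint is undone
   and filtering stops.
4. **Robustness.** The filter is re-run on link-weight-randomized
   copies of the network (LWRNs) to measure the stability of the
   extracted core.
5. **Enrichment.** Over-representation of an annotation (essential
   genes; planted backbone links) in the surviving network is tested
   with the upper-tail hypergeometric test, Benjamini–Hochberg-adjusted
   across a collection.

# Models and estimators

## Jackknife link weights

For a gene pair with expression vectors $x, y$ reduced to their $n$
pairwise-complete samples, the weight estimator is the plain mean of
the leave-one-out Pearson coefficients,

$$\bar r = \frac{1}{n}\sum_{i=1}^{n} r_{(-i)},$$

not the bias-corrected pseudo-value form. Each leave-one-out subset
needs at least three points, so $n \ge 4$ is required; a pair with zero
variance in any subset has no defined correlation and its link is
dropped (and counted). The link weight is $w = c\,\lvert \bar r\rvert$
with scale $c = 100$ by default, which maps correlations onto
integer-resolution weights for the discrete significance computation.
Pairwise-complete reduction (rather than casewise deletion over the
whole matrix) maximizes the usable samples per pair, matching common
practice for merged expression compendia. "Expressed" is operationalised
as non-missing — presence calls are upstream of the matrix this package
consumes — and genes present in fewer than 80% of samples (inclusive
boundary) are removed before weighting.

## Global link significance

The null model keeps the observed topology and assigns every link a
weight drawn i.i.d. from the empirical weight distribution $P(w)$,
discretized at bin width 1 on the $\times 100$ scale. The p-value of a
link $e = (i,j)$ with observed weight $w_e$ conditions on both endpoint
strengths:

$$p(w \mid s_i, s_j) \;\propto\; P(w)\, Q_{k_i-1}(s_i - w)\,
Q_{k_j-1}(s_j - w), \qquad
p_e = \Pr(W_e \ge w_e \mid S_i = s_i, S_j = s_j),$$

where $k$ is the degree, $s$ the strength (sum of incident weights,
taken at bin resolution so the conditioning is always attainable), and
$Q_m$ the $m$-fold self-convolution of $P$ ($Q_0$ a point mass at 0).
The two stars around a link share only the link itself, so the
conditional distribution factorises exactly; `null_oracle()` verifies
the convolution implementation against exhaustive enumeration over all
weight assignments on small graphs, and that enumeration is the ground
truth for this package's definition of the statistic.

Two structural consequences are worth internalising:

- A link incident to a **degree-1 node** has $p = 1$: its weight is
  fully determined by the leaf's strength, so it is maximally
  insignificant and is removed first. This is forced by the model, not
  a defect.
- A link is significant when it **dominates both endpoints**: when its
  weight is large relative to what the endpoint strengths, spread over
  the endpoint degrees, would predict. Absolute weight alone does not
  decide significance — this is exactly why the filter preserves
  low-weight links that a threshold would discard.

Convolutions are renormalised after every step to control drift;
agreement with enumeration is asserted to 1e-9 and observed far below
that.

## Constrained descending-p filtering

Removal order is: p-value descending, ties broken by ascending weight,
then by lexicographic link identifier — the canonical edge table
(endpoints sorted within a link, links sorted) makes runs byte-stable.
All anchor constraints are checked after every removal; by default both
constraints (receptor-complex ↔ NF-κB-like set, receptor-complex ↔
NFAT-like set) are enforced jointly in one pass, and the first
violation stops the whole run with the offending link restored. A
`sequential` mode (one full pass per constraint) is provided for
comparison; note that a later pass can remove links the earlier
constraint needed, so only the last constraint is guaranteed in its
final output.

Topology is recorded after every accepted removal: fraction of links
removed, fraction of nodes isolated (both are recorded because either
can serve as the percolation axis), diameter, relative giant-component
size $n_{rel} = n/N$, and mean size of the non-giant components
(singletons included, since link removal naturally produces them; 0
when only the giant component exists). The diameter is defined on the
largest connected component so that it stays finite as the network
fragments.

## LWRN robustness

For each fraction $f \in \{0.1, \dots, 0.9\}$ and iteration, a fraction
$f$ of links is selected uniformly and their weights permuted among
themselves — a permutation preserves the global weight distribution the
null model depends on; an alternative resample-with-replacement mode
exists behind a flag. P-values are recomputed on the randomized
network, the filter re-run with the same constraints, and six
statistics recorded: mean degree, mean path length over connected pairs
(hop counts), mean node and link betweenness (unweighted — the weights
are similarity scores, not distances), mean local clustering (0 for
degree < 2), and the link intersection with the reference filtered
network, reported both as a count and as a fraction of the reference
links because either normalization is defensible. Per-iteration seeds
are derived from the master seed and the (fraction, iteration) index.

## Enrichment

The over-representation p-value is the upper hypergeometric tail,
identical to a one-sided Fisher's exact test (a two-sided option
exists); the expected overlap is $nK/N$. The essentiality filter keeps
genes whose phenotype contains "lethality" (case-insensitive substring)
and whose annotation type contains neither "partial" nor "wean". The
background universe defaults to the genes of the input network but is
configurable, because published enrichment tables often use a
genome-wide background that cannot be reconstructed from the network
itself.

# The synthetic-data generator

`synthetic_scenario()` defines the study conditions the pipeline is
exercised under; all downstream stages are tested against it because
the real inputs (interaction databases, expression compendia, ortholog
lethality annotations) are version-bound external resources.

What it emulates, and how the pieces were designed:

- **Interactome**: a preferential-attachment skeleton (heavy-tailed
  degrees, as in real interactomes) with, by default, 200 genes and 800
  links; the planted-backbone analyses use 300 genes and 1500 links.
- **Backbone**: a path of `backbone_length` links joining one
  representative of each anchor set, routed through the skeleton's
  hubs. Two deliberate choices make the planted core the kind of
  structure the significance filter is designed to detect. First, core
  signalling proteins are modelled as hubs: under strength
  conditioning, a single dominant link at a node with many weak links
  is far more significant than the same link at a degree-2 node, so a
  backbone routed through random peripheral nodes would be
  statistically invisible — not because the filter is broken but
  because such a backbone genuinely does not stand out against the
  null. Second, backbone co-expression decays along the path as
  $\rho^{|i-j|}$ (a first-order autoregressive chain, emulating signal
  propagation down a cascade) rather than forming an exchangeable
  block: in an exchangeable high-correlation block every hub–hub link
  is equally heavy and no individual path link dominates its
  endpoints.
- **Anchor sets**: the terminal representatives and the non-
  representative members are dedicated pathway genes that touch the
  interactome only through the planted pathway (members attach to
  their representative like complex subunits), so anchor-to-anchor
  connectivity genuinely depends on the backbone and the stopping rule
  is exercised, not bypassed through the bulk network.
- **Expression**: multivariate normal with exchangeable within-module
  blocks ($\rho_{in}$ per module), background correlation $\rho_{out}$,
  and the AR(1) backbone, realised by shared latent factors — exact and
  positive semi-definite by construction. Configurations outside
  $0 \le \rho_{out} \le \min \rho_{in} \le 1$ are rejected as
  non-PSD; negative block correlations are outside the generator's
  supported range, since the planted structure only needs positive
  co-expression.
- **Missingness**: completely at random at `missing_rate` (default
  0.1) — the expressed-gene filter only needs a presence mask.
- **Essentiality**: Bernoulli labels at 0.15 background and 0.75 on
  backbone genes, so planted enrichment is detectable at desk scale.

One integer seed drives everything; the three generators draw from
streams derived deterministically from it, so scenarios are
reproducible as wholes and component-wise.

What the generator does **not** emulate: probe-level microarray
structure, batch effects, platform mixtures, correlated missingness,
database-specific interaction artifacts (complex expansion, taxonomy
mixing), or a literature-curated degree distribution. Passing tests
therefore demonstrate the pipeline's internal correctness and its
behaviour on networks with planted structure, not performance on any
particular real interactome.

# Numerical choices and degenerate inputs

- Bin width 1 on the ×100 weight scale; strengths are binned the same
  way so the conditional normalisation is never zero on native data
  (a zero normalisation can only arise with a foreign weight
  distribution and then falls back to the nearest reachable strength
  bin, flagged per link).
- Jackknife zero-variance detection uses a relative tolerance of 1e-12
  against the subset's sum of squares.
- An immediately-stopping filter run (first candidate removal already
  violates a constraint) returns the input network with an empty
  removal trace; an exhausted run (all links removable) reports
  `links_exhausted`.
- Empty networks yield all-zero topology records; filtered networks
  with no links yield zeroed LWRN statistics with a `degenerate` flag.

# Problem sizes

The shipped analyses use sizes chosen to keep a full run on a single
CPU interactive: the default end-to-end scenario is 200 genes × 60
samples with 800 links and a reduced LWRN design (fractions 0.1/0.5/0.9,
5 iterations; the full design of nine fractions × 30 iterations is the
package default for real analyses), and the planted-backbone scenario
is 300 genes × 200 samples with 1500 links and a 20-link backbone. At
these sizes the complete pipeline including the reduced robustness
experiment finishes in well under a minute.

# Known limitations

- The significance model treats the two stars of a link as independent
  given the link weight; this is exact for the pairwise conditioning
  used here but does not condition on the full joint strength sequence.
- Sequential constraint mode does not re-check earlier constraints
  (see above); joint mode is the default for exactly this reason.
- P-values are computed once on the input network and are not
  recomputed as links are removed, matching the stated procedure; a
  recompute-as-you-go variant would be a different algorithm.
- The AR(1) backbone makes distant backbone genes nearly uncorrelated;
  a real pathway with feedback could show longer-range co-expression.
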