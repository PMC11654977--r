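---
title: "Consensus inference of microbial association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus inference of microbial association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consenet)
```

## The problem

Microbial abundance tables are sparse, overdispersed, zero-inflated and
compositional, and the networks inferred from them by any single Gaussian
graphical model (GGM) estimator are notoriously irreproducible: different
estimators applied to the same data return very different edge sets. consenet
implements a consensus procedure built on a modified form of stability
selection that (i) quantifies, for every candidate edge and every estimator,
how reproducibly the edge is selected across data resamples, (ii) puts the
estimators on a common footing by equalizing the *density* of their
reproducible-edge sets under a mean-stability constraint, and (iii) merges the
per-edge selection frequencies into a single sparse, reproducible consensus
network.

## Model and procedure

For a count matrix $X$ ($n$ samples $\times$ $p$ taxa) each engine works on a
gaussianized transform of $X$ and estimates, along a regularization grid
$\lambda_1 > \dots > \lambda_K$, which of the $q = p(p-1)/2$ candidate edges
belong to the conditional-dependence graph (the support of the precision
matrix of a latent Gaussian model).

**Step 1 — selection frequencies.** $B$ subsamples of size $n' = \lfloor 0.8 n
\rfloor$ (for $n \le 144$; $\lfloor 10\sqrt{n} \rfloor$ beyond, the standard
StARS recommendation) are drawn without replacement and shared by all engines.
The engine is fit on every subsample and grid point, giving per-edge selection
frequencies $f_{ek} = \frac{1}{B} \sum_b 1\{e \in G^{b,k}\}$. Network-level
stability is one minus four times the mean Bernoulli variance,
$S_k = 1 - \frac{4}{q} \sum_e f_{ek}(1 - f_{ek})$, and the reproducible-edge
set at grid point $k$ and cutoff $c$ is $E^{\lambda_k}(c) = \{e : f_{ek} > c\}$
(strict inequality). Unlike classical StARS there is no final refit on the
full data: the frequencies themselves are the object of interest, which both
filters weakly supported edges out and makes frequencies comparable across
engines. The refit survives only inside the majority-rule baseline
(`mrc_consensus()`).

**Step 2 — density harmonization.** Selecting each engine's $\lambda$ at a
fixed stability produces edge sets of wildly different sizes, because equal
stability does not mean equal precision. `harmonize_densities()` instead
scans candidate target densities $d$ (descending through the union of
achievable reproducible-set sizes), maps each engine to the first grid point
reaching density $d$, and keeps the largest $d$ whose across-engine mean
stability is still at least the target (default 0.9). Every engine then
contributes a similar number of edges while the ensemble stays reproducible
on average. When no positive density meets the constraint the engines fall
back to their own StARS selections and the result is flagged unharmonized.

**Step 3 — summaries.** With $f_m$ the frequency an edge reaches at engine
$m$'s harmonized grid point, `summarize_frequencies()` computes

* `mean`: $\sum_m f_m / M$ — the most conservative summary at a high cutoff;
* `norm2`: $(\sum_m f_m^2)^{1/2} / M^{1/2}$ — skewed toward high frequencies;
* `ivw`: inverse-variance weighting with Bernoulli variances $f_m(1-f_m)$,
  after clamping $f_m$ into $[\epsilon, 1-\epsilon]$;
* `minp`: the binary vote $1\{\#\{m : f_m > c\} \ge p_{\min}\}$.

All summaries take method weights $w_m$ (default 1) and are thresholded at
$c$ (strict) by `consensus_graph()`. The arithmetic–quadratic mean inequality
makes the mean consensus a subset of the norm2 consensus at any shared
cutoff, which the test suite asserts on every run.

## The engine families

Published microbiome GGM methods cluster into three algorithmic families, and
results within a family are far more similar than across families. consenet
therefore ships the three families and instantiates them on different
normalizations to emulate a diverse ensemble (`default_engines()` gives six
members):

| engine        | family                 | normalization    |
|---------------|------------------------|------------------|
| `glasso-clr`  | graphical lasso        | CLR              |
| `mb-clr`      | neighborhood selection | CLR              |
| `mb-clr_npn`  | neighborhood selection | CLR + rank-gaussianization |
| `glasso-gmpr` | graphical lasso        | log GMPR-scaled  |
| `mb-gmpr`     | neighborhood selection | log GMPR-scaled  |
| `tree-gmpr`   | tree averaging         | log GMPR-scaled  |

The graphical lasso and the node-wise (Meinshausen–Bühlmann) lasso are solved
by a shared covariance-form coordinate-descent core (`src/gramlasso.cpp`)
that works directly on the $p \times p$ correlation matrix, so path cost does
not grow with $n$; the node-wise path is verified against `glmnet` in the
test suite and the graphical lasso against its KKT conditions and the
two-variable closed form. Tree averaging scores each edge by its probability
of appearing in a random spanning tree weighted by pairwise Gaussian mutual
information $-\tfrac12\log(1-r^2)$, computed exactly with the weighted
matrix-tree theorem and verified against exhaustive tree enumeration for all
connected graphs on up to six vertices.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `B` | 40 | resamples; frequencies live on the lattice $\{0, 1/B, \dots, 1\}$ |
| `K` | 30 | grid length per engine |
| grid range | $[0.01\,\lambda_{\max}, \lambda_{\max}]$, log-spaced | penalty engines; $\lambda_{\max}$ is the largest absolute sample correlation, above which paths are empty |
| tree grid | 30 thresholds, linear in $(0.02, 0.98)$ | probability scale |
| `stab` | 0.9 | mean-stability target of the harmonization |
| `cutoff` (c) | 0.9 | strict frequency/score threshold |
| `p_min` | 3 | minp vote count |
| `clamp_eps` | $1/(2B)$ | IVW clamping; half the frequency-lattice spacing, the least-informative fix for zero-variance frequencies |
| `pseudocount` | 1 | added before all log transforms |
| `prevalence` | 0.5 (when filtering) | keep taxa present in strictly more than this fraction of samples |

## Numerical choices

* Precision entries with magnitude $\le 10^{-8}$ count as zero; coordinate
  descent produces exact zeros via soft-thresholding, so supports are not
  tolerance-sensitive in practice.
* Raw penalized paths can be non-monotone in $\lambda$; each subsample path
  is corrected by cumulative union along decreasing $\lambda$, and stability
  and density profiles get a monotone envelope (running min / running max)
  before any selection. This matches the monotone reading of
  density-vs-stability curves assumed by the harmonization.
* The graphical lasso declares convergence when the mean absolute change of
  the working covariance falls below $10^{-4}$ times the mean absolute
  off-diagonal of the input correlation (the classical criterion); a grid
  point that fails to converge is retried once with a $10^{-3}$ ridge and
  flagged if still failing. Inner lasso solves use tolerance $10^{-4}$
  with warm starts along the path.
* Ties in the rank-gaussianization take average ranks; all zeros of a count
  column form one tie group; a constant column maps to zeros with a warning.
* Perfect correlations are clamped ($r^2 \le 1 - 10^{-12}$) before the tree
  weights $-\tfrac12 \log(1 - r^2)$.
* In per-subsample fits a taxon that became constant is given zero
  correlation to everything rather than aborting the fit; a whole-engine
  failure on a subsample counts that subsample's graph as empty and is
  logged, so one bad resample cannot abort a frequency table.
* GMPR factors follow the pairwise-median definition: the factor of sample
  $i$ is the geometric mean over other samples $j$ of the median count ratio
  on taxa positive in both, rescaled to geometric mean one.

## The synthetic benchmark

`simulate_dataset()` draws a cluster graph (balanced groups, independent
within-group edges, no between-group edges — a caricature of microbial
guilds), builds the precision matrix as the graph Laplacian plus a ridge
(default 0.1; a pure Laplacian is singular, and the ridge keeps the support
exactly equal to the truth adjacency), inverts and rescales it to a
correlation matrix, and pushes latent Gaussian samples through per-taxon
quantile functions via a Gaussian copula. Marginals are either empirical
quantile tables from a reference count table (`ecdf_marginals()`) or
zero-inflated negative binomials (`zinb_marginals()`), so the full test suite
runs without any external dataset. Default ZINB ranges are
$\pi \sim U[0.1, 0.6]$, $\mu$ log-uniform on $[1, 200]$,
$\theta \sim U[0.1, 2]$.

The defaults aim at a community of ~15 taxa per cluster with within-cluster
edge probability 0.3, giving truth graphs of roughly 200 edges at $p = 100$ —
the density regime where harmonized selections land in real-size microbiome
analyses. The benchmark marginals are rejection-sampled so each taxon's total
zero probability stays below 0.5: the simulated community then looks like one
that already passed the customary 50% prevalence filter, mirroring analyses
that estimate marginals from prevalence-filtered species, and avoiding
post-hoc node removal that would change $p$ and the truth graph.

What the generator deliberately does not emulate: sequencing-depth variation
and compositional closure (counts are drawn independently per taxon given the
latent Gaussian, so normalization steps are exercised but not stressed),
covariate effects, taxon correlation between zero inflation and abundance,
and the heavy phylogenetic structure of real communities. Passing benchmarks
therefore demonstrate correct recovery of a known conditional-dependence
structure under realistic marginals, not end-to-end performance on real
sequencing runs.

## Validation protocol and problem sizes

The automated suite checks exact formula oracles and combinatorial oracle
equivalences (spanning-tree enumeration up to $p = 6$; node-wise lasso vs
glmnet; glasso KKT), structural invariants over randomized toy ensembles, and
a scaled-down replicated benchmark: $p = 100$ taxa, $B = 20$ resamples,
$K = 25$ grid points, 10 datasets each at $n = 50$ and $n = 100$ and 5 at
$n = 500$, scoring the mean-summary consensus and every single
stability-selected engine against the known truth. These sizes keep a full
run on one core in the tens of minutes while preserving the qualitative
pattern: the consensus is sparser and more precise than the median single
engine, at a recall cost that shrinks with $n$.

## Known limitations

* The harmonization assumes the enveloped stability and density profiles are
  monotone surrogates of precision; engines whose stability barely moves
  along the grid (tree averaging on strong data) contribute little contrast
  to the mean-stability constraint.
* The glasso family is systematically denser and less precise than
  neighborhood selection on clustered truths, because marginal correlations
  within a cluster are strong even for non-edges; this is a property of the
  estimator, not a defect of the implementation, and is the very
  heterogeneity the consensus step is designed to absorb.
* An unharmonized fallback (no density satisfying the mean-stability
  constraint) signals that the data cannot support a reproducible consensus
  at the requested stability; lowering `stab` or `cutoff` trades
  reproducibility for recall explicitly rather than silently.
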