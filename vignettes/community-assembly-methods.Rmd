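---
title: "Quantifying community assembly and co-occurrence: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying community assembly and co-occurrence: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters that matter, what
the synthetic-data generator does and does not emulate, and the design
choices we made where the methodology literature leaves the design open.

## 1. The phylogenetic null-model framework

### Model and assumptions

The framework infers assembly processes from two complementary
pairwise statistics.

**βMNTD / βNTI.** For samples $k$ and $m$ with relative abundances
$f_{jk}$ and patristic distances $d(j,j')$,

$$\beta\mathrm{MNTD}(k,m) = \tfrac12\Big[\sum_{j \in k} f_{jk}\,
\min_{j' \in m} d(j,j') + \sum_{j \in m} f_{jm}\,\min_{j' \in k}
d(j,j')\Big].$$

An OTU shared by both samples contributes distance zero (its nearest
taxon in the other community is itself). The null distribution is
obtained by shuffling OTU identities across the tips of the phylogeny
("taxa.labels" convention) and recomputing βMNTD; βNTI is the per-pair
z-score. The inference is only meaningful if ecological niches carry
phylogenetic signal at short phylogenetic distances — which is why
`mantel_correlogram()` exists and why the synthetic generator evolves
niche traits by Brownian motion, making the assumption true by
construction.

**Raup–Crick on Bray–Curtis.** The null assembles each sample anew,
preserving its observed richness and read total: OTUs are drawn without
replacement with probability proportional to their occurrence frequency,
one read each, and remaining reads are distributed multinomially with
probability proportional to metacommunity relative abundance.
$RC = 2\,\frac{\#(\mathrm{null} < \mathrm{obs}) +
\tfrac12\#(\mathrm{null} = \mathrm{obs})}{n_\mathrm{null}} - 1 \in
[-1, 1]$.

**Classification.** βNTI > 2 → heterogeneous selection; βNTI < −2 →
homogeneous selection; otherwise RC > 0.95 → dispersal limitation,
RC < −0.95 → homogenizing dispersal, else drift. The 2 / 0.95 thresholds
are the standard convention of the null-model framework (they are not
derived quantities); both are exposed as arguments of
`classify_processes()`.

### Numerical and design choices

* **Standardization is per pair** (each pair's own null mean and sd),
  not per matrix. A pair whose null sd is zero — e.g. two samples with
  identical composition, where every tip relabeling still gives
  βMNTD = 0 — has no well-defined z-score and is reported `NA` with a
  warning rather than silently set to 0.
* **Null tables for RC are drawn once per randomization for all
  samples**, and all pairwise Bray–Curtis values of that null table are
  compared against the observed matrix. The marginal null distribution
  per pair is identical to drawing pair-specific nulls at a fraction of
  the cost; only the (unused) dependence *between* pairs within one
  randomization differs.
* **Ties** between null and observed Bray–Curtis contribute one half,
  the standard Raup–Crick convention. With abundance data exact ties are
  rare but possible (e.g. identical low-richness samples), so the
  boundary value −1 is attained only up to ties.
* **Calibration bias to expect.** Even on communities generated by the
  null procedure itself, the RC mean is slightly negative at small
  sample numbers (we measure ≈ −0.2 to −0.3 at 12–16 samples) because
  the null conditions on occurrence frequencies and abundances
  *re-estimated from the very table being tested*; the observed samples
  are self-consistent with those marginals, independent null draws are
  not. The tail behaviour (|RC| > 0.95 in ~5–10% of pairs) is the
  operative property for classification and is what the acceptance suite
  asserts. βNTI shows no such offset beyond Monte-Carlo noise.

## 2. The Sloan neutral community model

The model treats a local community as a sample of size $N$ (reads) from
a metacommunity in which OTU $i$ has relative abundance $p_i$, with
migration parameter $m$; the stationary local relative abundance is
Beta-distributed with concentration $Nm$. The fit relates each OTU's
*occurrence frequency* across samples to $p_i$.

Two detection models are implemented:

* `detection = "exact"` (default): the probability that at least one of
  $R$ reads hits the OTU under Beta-binomial sampling,
  $\hat f_i = 1 - \mathrm{B}(Nm\,p_i,\; Nm(1-p_i)+R)\,/\,
  \mathrm{B}(Nm\,p_i,\; Nm(1-p_i))$, with $R$ the mean sample depth.
* `detection = "threshold"`: the classical approximation
  $\hat f_i = 1 - F_\mathrm{Beta}(d;\, Nm\,p_i,\, Nm(1-p_i))$ with
  detection limit $d = 1/R$.

We made the exact model the default after observing that the threshold
approximation overestimates $Nm$ by roughly 25–30% on data simulated
from the model's own generative process (Dirichlet composition, then
multinomial reads) — enough that a tight bootstrap confidence interval
never covers the truth. The threshold variant is retained for
comparability with published fits, which almost universally use it; its
$R^2$ is essentially as high, so goodness-of-fit comparisons are
unaffected, but its $m$ runs high.

The 95% band used to classify OTUs as above/within/below the prediction
is, by default, the **exact binomial prediction interval** for an
observed frequency out of $n$ samples. A Wilson score interval (common
in published code) is available via `band = "wilson"`, but note a
structural defect: a Wilson interval around a nonzero predicted
frequency never contains 0, so every rare OTU that happens to be absent
falls "below" it, and the within-band fraction on perfectly neutral data
is ~75% rather than the nominal 95%. The prediction band attains ~95–97%
(slightly conservative because frequencies are discrete).

$Nm$ is fit by bounded scalar least squares on untransformed
frequencies (golden-section search on $\log Nm \in [\log 10^{-2},
\log 10^8]$); the bootstrap resamples OTUs with replacement (default
1,000 replicates, percentile intervals).

## 3. Distance-matrix statistics

`mantel()` correlates unfolded lower triangles and permutes rows and
columns of the second matrix simultaneously; the p-value is one-sided
($r_\mathrm{perm} \ge r_\mathrm{obs}$), resolution $1/(n_\mathrm{perm}+1)$.
`partial_mantel()` correlates the residuals of both matrices after OLS
on the controls and permutes the first matrix; samples carrying missing
pairs (e.g. undefined βNTI) are dropped before permutation so the
permutation distribution stays exchangeable. Residual standard
deviations below $10^{-9}$ (relative) are treated as zero so that a
control identical to a matrix yields exactly $r = 0$ rather than noise
correlation. `mrm()` is OLS on unfolded matrices with response-matrix
permutation; with a single predictor its $R^2$ equals the squared Mantel
correlation by construction.

`mantel_correlogram()` uses equal-width distance classes (count by
Sturges' rule on the number of pairs unless given), the conventional
sign flip so that positive values mean similarity at that distance, a
two-sided permutation test per class, and progressive Holm correction
(class $k$ is corrected across classes $1..k$). Classes with fewer than
two pairs are dropped with a message.

Variation partitioning uses CCA (following the upstream methodology)
with environmental axes retained by the Kaiser–Guttman rule and dbMEM
spatial predictors built by `vegan::pcnm` (truncation at the longest
minimum-spanning-tree edge). Two refinements proved necessary: MEM
vectors are restricted to those with **positive Moran's I** under the
truncation-neighbourhood weights, and then **forward-selected** against
the community (`vegan::ordistep`, 199 permutations). Without selection,
ten-plus unselected eigenvectors soak up inertia on 30-sample designs
and the spurious "spatial" fraction reaches ~0.3–0.4 on pure noise; with
selection it drops near zero. Fractions are raw shares of total inertia
(adjusted $R^2$ is not well defined for CCA), so they should be compared
within a dataset, not across datasets of different predictor counts.

## 4. SparCC

Correlations between unobserved absolute abundances are estimated from
compositional counts via log-ratio variances
$t_{ij} = \mathrm{Var}\,\log(x_i/x_j)$ and the sparsity assumption.
Basis variances solve the least-squares system
$t_{ij} \approx \omega_i^2 + \omega_j^2$ over included pairs; each
exclusion round removes the single most-correlated pair above the
exclusion threshold (default 0.1, at most 10 rounds) and re-solves.
Fractions come from a Dirichlet posterior (counts + 1); the point
estimate is the median over `n_iter = 20` Dirichlet draws. Pseudo
p-values shuffle each OTU's counts independently across samples
(`n_bootstrap` null datasets, two-sided, with the +1 correction), then
Benjamini–Hochberg. Note the attainable adjusted p is floored at
$\approx \frac{1}{n_\mathrm{bootstrap}+1}\cdot
\frac{\#\mathrm{pairs}}{\#\mathrm{discoveries}}$: clearing adjusted
p < 0.01 on hundreds of OTUs requires on the order of 1,000 bootstrap
datasets. Negative basis-variance solutions (possible after aggressive
exclusion) are floored at $10^{-10}$ and the implied correlations
clipped to $[-1, 1]$.

## 5. Networks, topology, node roles

Edges require $|r| \ge r_\mathrm{min}$ (inclusive — a correlation of
exactly 0.7 is kept) *and* adjusted $p < p_\mathrm{max}$ (strict).
Isolated nodes are dropped. All topology metrics are computed on the
unweighted, unsigned simple graph; edge signs enter only the
positive/negative edge percentages. Diameter and average path length
refer to the largest connected component, since both are undefined on a
disconnected graph and the convention in the source tooling (Gephi) is
the same. Modules come from Louvain modularity optimization under a
fixed seed (the algorithm is stochastic; the seed is part of the
result's provenance). Within-module degree z-scores are defined as 0 in
modules whose within-degrees have zero spread (e.g. cliques), rather
than NaN, so classifications stay total. The participation coefficient
of a node with all links in its own module is 0; with links spread over
all $N_M$ modules it is bounded by $1 - 1/N_M$.

## 6. The synthetic-data generator

The generator emulates a coast-to-basin survey: stations on a ~500 km
transect, up to three depth layers, replicate samples per
station × layer cell (default 4 × 3 × 7 = 84 samples), and a
temperature-like gradient that warms offshore at the surface and cools
offshore at depth, with within-cell noise (default sd 0.3 °C).
Communities are assembled from:

1. a log-normal metacommunity (meanlog 0, sdlog 1.5 — steep, realistic
   rank-abundance curves);
2. station source pools: per-station log-normal perturbations of the
   metacommunity (sd `pool_noise_sd`), mixed across stations within a
   layer by the kernel $e^{-d_\mathrm{km}/\lambda}$ (layers are never
   mixed, emulating stratification);
3. a Gaussian environmental filter
   $e^{-s\,(\mathrm{trait}-\mathrm{env})^2}$ on Brownian niche traits
   rescaled to the gradient's range;
4. a Dirichlet resampling step with concentration
   $m \cdot \mathrm{read\_depth}$ (demographic drift; the same
   construction the neutral model assumes), then a multinomial read
   draw.

The drift-only scenario keeps steps 1 and 4. We deliberately did *not*
define drift as plain multinomial resampling: at realistic read depths
two multinomial draws from one pool are far *more* similar than the
Raup–Crick null expects (RC ≈ −1, i.e. homogenizing dispersal), because
the null re-draws occupancy. Demographic stochasticity at the level the
neutral model itself estimates for such communities (m of order 0.1)
is what "drift" means in this framework, and that is the default used in
the ground-truth recovery suite. The kernel scale and `pool_noise_sd`
knobs for the dispersal-limitation scenario (10 km against ~170 km
station spacing; sd 2) encode "effectively disjoint station pools".

What the generator does **not** emulate: sequencing error and chimeras
(counts are exact multinomial draws), taxonomic structure, diurnal
dynamics beyond replicate sampling, biotic interaction networks (OTUs
are conditionally independent given the environment — so a green
recovery test says the *statistics* behave correctly on communities with
known process mix, not that real protist–bacteria interactions are
captured), and the correlation structure of multiple environmental
variables (the covariates besides temperature are decorative noise).

## 7. Known limitations

* βNTI with 1,000 randomizations carries null-sampling noise of roughly
  ±0.3 in the index; process fractions move by a few percent between
  seeds. This matches the resampling-stability bound asserted in the
  tests.
* The Raup–Crick self-calibration offset at small $n$ (see §1) means
  absolute RC means should not be over-interpreted on designs with
  fewer than ~20 samples.
* The prevalence filter reads "more than 60%" as strict, and is applied
  after any balanced subsampling; both choices are configurable but
  affect which OTUs enter networks.
* CCA variation-partitioning fractions are not adjusted for predictor
  count; use the reported `n_env_axes` / `n_mem` when comparing.
* The NCM fit assumes a single metacommunity for all samples; fitting
  it to strongly selection-structured data yields low or negative $R^2$
  (visible in the README example), which is a diagnostic, not an error.
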