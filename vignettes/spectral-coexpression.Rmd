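---
title: "Differential co-expression of gene sets via graph spectral distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential co-expression of gene sets via graph spectral distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexspec)
```

## The problem

Two genes are co-expressed when their expression levels are statistically
dependent across samples. A gene set is *differentially co-expressed*
between two phenotypes when the dependence structure among its genes — its
co-expression graph — differs between the phenotypes, even if no single
gene changes its average expression. Mutations in a transcription factor's
activation domain, or post-translational modifications of a regulator, can
rewire a pathway without shifting any mean expression level, so differential
co-expression analysis complements, rather than repeats, differential
expression analysis.

`coexspec` tests, for each gene set in a collection, the null hypothesis
that the two phenotypes' co-expression graphs are structurally equal,
H~0~: Θ = 0 against H~1~: Θ > 0, where Θ is a nonnegative distance between
graph structural features. The primary Θ is the Jensen–Shannon divergence
between the *spectral densities* of the two graphs; alternatives based on
degree distributions, centralities, clustering coefficients, shortest paths,
and spectral entropy are available through the same interface.

## From expression data to a graph

For one phenotype's samples and one gene set with $n_V$ genes, every gene
pair gets a correlation (Spearman by default; Pearson and Kendall are
available) and a two-sided p-value. Spearman and Pearson p-values use the t
approximation on $n - 2$ degrees of freedom; since the smallest recommended
group size is around 20 samples, the difference from exact permutation
p-values is negligible, and the vectorized approximation is what makes
label-permutation testing affordable. Kendall's tau-b uses the standard
normal approximation.

The test result is mapped onto an association degree in $[0, 1]$ on one of
three scales: $|r|$, $1 - p$, or $1 - p^{BH}$, where $p^{BH}$ is the
Benjamini–Hochberg adjustment over the $n_V (n_V - 1)/2$ pairs of the set.
Adjustment is applied within each set because every set's sub-network is
built and permutation-tested independently; the adjusted scale sharpens the
contrast between supported and unsupported edges. The default graph is
*weighted*: the adjacency matrix simply is the degree matrix (symmetric,
zero diagonal). An unweighted mode thresholds the degrees instead. The
default pipeline used in all simulations is the weighted Spearman/FDR one.

Genes that are constant within a group — which label permutations can
create — degrade to zero association with a warning rather than erroring,
so the permutation null is always computable.

## Spectral analysis

The spectrum of a graph is the multiset of eigenvalues of its adjacency
matrix $A$; it encodes diameter, walk counts, clique structure, and more,
and its distribution characterizes a graph ensemble better than individual
summary statistics. Eigenvalues are divided by $n_V$ (following the
definition of the spectral density of a graph family) and their density
$\rho(\lambda)$ is estimated by a Gaussian kernel. Because the two graphs in
a comparison always share $n_V$, this rescaling shifts both entropies by the
same additive constant and leaves all divergence-based p-values unchanged;
the normalization constant is therefore inconsequential for testing and is
fixed at $n_V$ once.

Two bandwidth criteria are provided. The default, Sturges', uses the bin
width of a Sturges histogram, $h = \mathrm{range} / \lceil \log_2 n + 1
\rceil$, read as a Gaussian kernel bandwidth; Silverman's rule of thumb
$h = 0.9 \min(\hat\sigma, \mathrm{IQR}/1.34)\, n^{-1/5}$ is the alternative.
If the spread is degenerate (all eigenvalues equal, e.g. an edgeless graph)
the bandwidth falls back to $10^{-3}\max(1, |\lambda_{max}|)$ so the
estimator never divides by zero. Densities are evaluated on 512 grid points
and renormalized so their trapezoid integral is exactly 1; at 512 points the
trapezoid error is far below the resolution of a permutation test.

From $\rho$ we compute, with natural logarithms throughout (everything in
nats):

* **spectral entropy** $H(\rho) = -\int \rho \log \rho \, d\lambda$ with
  $0 \log 0 = 0$ — the structural randomness of the graph (a differential
  entropy, so possibly negative);
* **Kullback–Leibler divergence** $KL(\rho_1 | \rho_2) = \int \rho_1
  \log(\rho_1/\rho_2) \, d\lambda$, infinite when the support of the
  reference $\rho_2$ does not contain that of $\rho_1$;
* **Jensen–Shannon divergence** $JS(\rho_1, \rho_2) = \tfrac12 KL(\rho_1 |
  \rho_M) + \tfrac12 KL(\rho_2 | \rho_M)$, $\rho_M = \tfrac12(\rho_1 +
  \rho_2)$ — symmetric, always finite, bounded by $\log 2 \approx 0.693$,
  and with $\sqrt{JS}$ a metric.

Comparisons require a common measure, so two spectra are always evaluated on
one shared grid spanning the pooled eigenvalue range extended by three times
the larger of the two bandwidths (each graph keeps its own bandwidth). A
numerical floor of $10^{-12}$ is applied inside logarithms only, preserving
the $0\log 0 = 0$ convention while avoiding spurious $-\infty$ from
round-off on renormalized densities.

## Other graph distances

Beyond `spectral_js`, `graph_distance()` implements: the Jensen–Shannon
divergence between degree (node-strength) distributions, estimated with the
same kernel machinery; Euclidean distances between degree-centrality,
eigenvector-centrality, and local-clustering vectors, divided by $n_V$ so
they read as per-gene discrepancies (any monotone rescaling leaves
permutation p-values unchanged, a property the tests assert); and absolute
differences of average shortest path length and spectral entropy.

Feature conventions, chosen where the field has several:

* Weighted shortest-path length uses reciprocal weights $1/w$ — strong
  association means short distance — and averages over reachable pairs
  only, keeping the statistic finite on sparse permuted graphs.
* Weighted clustering is Onnela's geometric-mean coefficient on
  max-normalized weights; on 0/1 weights it reduces to the classical
  triangle fraction, so one formula serves both modes.
* Betweenness and closeness are restricted to unweighted graphs. Closeness
  of a node is (number of reachable nodes) / (total distance to them),
  which equals $(n_V - 1)/\sum d$ on connected graphs and handles
  disconnected ones per component; isolated nodes score 0.
* Eigenvector centrality is the Perron eigenvector of $A$, nonnegative,
  unit $L_2$ norm.

## The permutation test

Given the observed distance $\Theta_{obs}$, the null distribution is built
by shuffling the sample-to-phenotype assignment uniformly at random
(group sizes fixed) and recomputing both graphs and their distance $B$
times. The p-value includes the observed value in the null set,

$$p = \frac{1 + \#\{b : \Theta_b \ge \Theta_{obs}\}}{1 + B},$$

which guarantees $p \ge 1/(B+1) > 0$ and makes the test exact-level under
exchangeability; p-values live on the lattice $k/(B+1)$. Across a
collection, sets are intersected with the expression genes, sets smaller
than `min_size` (default 20 — smaller sets make network-feature estimates
unstable) are dropped, and BH q-values are attached across the surviving
sets. Each set's permutation stream is seeded by a hash of the master seed
and the set name, so adding or removing sets never perturbs another set's
p-value. Reasonable permutation counts are $B = 1000$ for simulation work
and $B = 10000$ for a real collection-level analysis.

## The synthetic-data generator and the Monte Carlo experiments

`generate_expression()` draws a gene-by-sample matrix from a multivariate
normal with block-constant correlation: genes within a block share pairwise
correlation $\rho$, all other pairs are independent, sampling via the
Cholesky factor of the implied correlation matrix. The default pool — 50
genes in 5 blocks of 10 at $\rho = 0.6$, 200 samples, unit marginal
variance — emulates a pool of microarrays with realistic co-expression
modules at moderate strength. What it does *not* emulate: heavy-tailed or
heteroscedastic expression, overlapping modules, between-block correlation,
or batch structure. Passing the calibration and power checks on this pool
therefore demonstrates properties of the *test* (validity under the null,
sensitivity to destroyed correlation), not agreement with any particular
real dataset's effect sizes.

Two experiments run on the pool:

* **False-positive rate** (`fpr_experiment`): each replicate resamples two
  groups — 65 and 30 columns by default — *with replacement* from the same
  pool (so H~0~ holds by construction; resampled columns are i.i.d. draws,
  hence exchangeable), draws a random gene set, and records the
  permutation p-value. The rejection rate at level $\alpha$ should match
  $\alpha$.
* **Power** (`power_experiment`): each replicate draws $2 \times 40$
  columns, splits them into two groups, and destroys the co-expression of
  a proportion $\gamma$ of a 50-gene set in the second group only, by
  independently permuting each selected gene's values across that group's
  samples. Rejection rates over a dense $\alpha$ grid
  ($0.005, 0.010, \ldots, 1$) are summarized by the trapezoidal area under
  the power-versus-$\alpha$ curve, anchored at $(0, 0)$: AUC $\approx 0.5$
  under the null, approaching 1 for a powerful test.

The package's standard experiment size is 200 replicates of 200
permutations each, with binomial-standard-error tolerances sized
accordingly; both counts are plain arguments, so larger studies are a
matter of patience. Per-replicate seeds are derived from the master seed
and the replicate index, making reports reproducible and independent of
execution order. At $\gamma = 0.5$ on this pool the spectral test sits deep
in its saturation regime (AUC above 0.95); intermediate-$\gamma$ power
depends on the substrate's correlation structure and is not comparable
across substrates, which is why only the saturation point and the
$\gamma = 0$ null limit are treated as benchmarks.

## Numerical choices and degenerate inputs

* Trapezoid rule on the 512-point grid for all integrals (entropy, KL, JS,
  AUC).
* Constant genes: zero association plus a warning (never an error inside
  permutation loops).
* Edgeless graphs: spectrum all zeros, degenerate-bandwidth fallback,
  average path 0; eigenvector centrality is undefined and errors (reported
  as `NA` in `set_properties()`).
* Probe collapse: one row per gene, keeping the probe with maximal mean
  expression across samples; exact ties break to the lexicographically
  smallest probe id.
* Correlations are clamped to $[-1, 1]$ before p-value computation;
  $|r| = 1$ maps to $p = 0$.
* Ties in gene rankings break alphabetically by symbol.

## Limitations

Only two-phenotype designs are supported. The FDR scale adjusts p-values
within each gene set, not across the whole genome; the two choices give
different edge weights, and the within-set scope is the one compatible with
testing sets independently. Betweenness/closeness are unavailable for
weighted graphs. The spectral test detects distributional change in the
spectrum; a rewiring that exactly preserves the spectrum (isospectral
graphs) is invisible to `spectral_js`, which is one reason the other
distance kinds exist.
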