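# coexspec

Differential co-expression analysis of gene sets by comparing the spectral
distributions of gene co-expression graphs.

## What problem it solves, and for whom

Gene-set methods such as GSEA detect coordinated shifts in *average*
expression, but a pathway can be dysregulated without any gene changing its
mean — for example when a mutated transcription factor rewires its targets.
Such changes show up in the *correlation structure* among the pathway's
genes. `coexspec` is for analysts with a two-phenotype expression study
(genes × samples matrix, sample labels, and a gene-set collection such as
MSigDB canonical pathways) who want to know which sets changed their
co-expression network, with honest permutation-based significance.

## The statistic

For each gene set and each phenotype, a weighted graph is built over the
set's genes: by default edge weights are `1 − p_BH`, one minus the
Benjamini–Hochberg-adjusted p-value of the Spearman correlation test
between the two genes, adjusted over the set's gene pairs (absolute
correlation and unadjusted `1 − p` scales, Pearson/Kendall, and thresholded
unweighted graphs are also available). The two phenotype graphs *G₁*, *G₂*
are compared through the spectral distribution: with ρᵢ the Gaussian-kernel
density estimate of the eigenvalues of the adjacency matrix of *Gᵢ*
(rescaled by the vertex count, evaluated on a shared grid), the test
statistic is the Jensen–Shannon divergence

  Θ = JS(ρ₁, ρ₂) = ½ KL(ρ₁ | ρ_M) + ½ KL(ρ₂ | ρ_M),  ρ_M = ½(ρ₁ + ρ₂),

which is 0 iff the spectral densities coincide and at most log 2. H₀: Θ = 0
is tested by permuting sample labels: p = (1 + #{Θ_perm ≥ Θ_obs})/(1 + B).
Alternative distance statistics — degree-distribution JS, centrality /
clustering Euclidean distances (per-gene scaled), shortest-path and
spectral-entropy differences — plug into the same test. Across a collection,
q-values are BH-adjusted over the surviving sets. Spectral entropy
H(ρ) = −∫ρ log ρ, per-phenotype network properties, gene rankings, and
single-gene t / Wilcoxon tests support follow-up of the hits.

## Worked example

Synthetic two-phenotype data where one 10-gene set has its co-expression
destroyed in phenotype B and another is left intact:

```r
library(coexspec)
set.seed(42)
pool <- generate_expression(simulation_config(
  n_genes = 40, n_samples = 400, block_sizes = rep(10, 4), seed = 42))
x <- pool[, 1:60]; colnames(x) <- paste0("S", 1:60)
labels <- setNames(rep(c("A", "B"), each = 30), colnames(x))
for (g in 1:10) x[g, 31:60] <- x[g, 31:60][sample.int(30)]  # rewire set 1 in B

sets <- list(rewired = rownames(pool)[1:10], intact = rownames(pool)[11:20])
analyze_collection(x, labels, sets, B = 1000, min_size = 10, seed = 7)
#>   set_name set_size statistic_name statistic  p_value q_value
#> 1  rewired       10    spectral_js  2.04e-01 0.000999   0.002
#> 2   intact       10    spectral_js  7.03e-06 0.910090   0.910
```

The rewired set's spectral JS divergence (0.204) is far outside the
permutation null — p hits the lattice floor 1/(B+1) — while the intact set
is indistinguishable from noise. Per-phenotype network summaries show what
changed:

```r
g1 <- coexpression_graph(x[rownames(pool)[1:10], 1:30])   # phenotype A
g2 <- coexpression_graph(x[rownames(pool)[1:10], 31:60])  # phenotype B
set_properties(g1)
#> average degree:        8.9941
#> average clustering:    0.9993
#> spectral entropy:      0.1169
#> average shortest path: 1.0007
set_properties(g2)
#> average degree:        1.9027
#> average clustering:    0.3338
#> spectral entropy:      -1.0793
#> average shortest path: 4.7842
```

A dense, tightly clustered module in A collapses to a sparse one in B.
`rank_genes(g1, "degree")`, `differential_expression()`, and
`edge_difference_matrix()` drill further into a hit.

For file-based workflows there is a thin command-line front end at
`inst/cli/coexspec.R` (`analyze`, `simulate fpr`, `simulate power`) and a
full analysis template at `inst/scripts/real_data_analysis.R` (expression
TSV + two-column/CLS labels + GMT in, result TSV out).

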