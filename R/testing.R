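# Deterministic seed derivation: per-set / per-replicate streams independent
# of execution order. All arithmetic stays below 2^53 so results are exact in
# doubles; outputs lie in [1, 2^31 - 2].
.seed_mod <- 2147483647
hash_key <- function(key) {
  h <- 0
  for (k in utf8ToInt(as.character(key))) h <- (h * 31 + k) %% .seed_mod
  h
}
derive_seed <- function(master, key) {
  h <- (hash_key(key) * 31 + (master %% .seed_mod)) %% .seed_mod
  as.integer(h %% (.seed_mod - 1L) + 1)
}

# Permutation p-value with the observed statistic included in the null set:
# p = (1 + #{null >= obs}) / (1 + B). Guarantees p > 0 and test validity;
# invariant under any strictly monotone rescaling of the statistic.
perm_pvalue <- function(obs, null) {
  (1 + sum(null >= obs)) / (1 + length(null))
}

split_by_label <- function(labels) {
  lv <- unique(labels)
  if (length(lv) != 2L) stop("exactly two phenotypes required")
  list(which(labels == lv[1L]), which(labels == lv[2L]))
}

# Core statistic evaluation on an explicit two-group split of columns.
statistic_for_split <- function(x, idx1, idx2, config, kind, criterion, warn = FALSE) {
  g1 <- coexpression_graph(x[, idx1, drop = FALSE], config, warn = warn)
  g2 <- coexpression_graph(x[, idx2, drop = FALSE], config, warn = warn)
  graph_distance(g1, g2, kind, criterion)
}

prepare_set <- function(expr, labels, gene_set) {
  labels <- align_labels(labels, expr)
  genes <- gene_set[gene_set %in% rownames(expr)]
  if (length(genes) < 2L)
    stop("gene set has fewer than 2 genes present in the expression matrix")
  if (any(table(labels) < 3L))
    stop("each phenotype needs at least 3 samples for correlation estimation")
  list(x = expr[genes, , drop = FALSE], labels = labels, genes = genes)
}

#' Observed graph-distance statistic for one gene set
#'
#' Builds one co-expression graph per phenotype (restricting the expression
#' matrix to the gene set and to each phenotype's samples) and returns the
#' chosen graph-distance statistic between them. This is the observed value
#' of the test statistic for H0: distance = 0.
#'
#' @param expr Expression matrix (genes x samples).
#' @param labels Phenotype labels ([read_labels()] output or a named vector).
#' @param gene_set Character vector of gene symbols.
#' @param config An [association_config()].
#' @param kind Statistic name, see [graph_distance()].
#' @param criterion Bandwidth criterion for density-based statistics.
#' @return A nonnegative scalar.
#' @export
observed_statistic <- function(expr, labels, gene_set,
                               config = association_config(),
                               kind = "spectral_js",
                               criterion = c("sturges", "silverman")) {
  criterion <- match.arg(criterion)
  ps <- prepare_set(expr, labels, gene_set)
  idx <- split_by_label(ps$labels)
  statistic_for_split(ps$x, idx[[1L]], idx[[2L]], config, kind, criterion, warn = TRUE)
}

#' Permutation test of differential co-expression for one gene set
#'
#' Tests H0: the two phenotypes' co-expression graphs are equal (graph
#' distance 0) against H1: distance > 0. The null distribution is built by
#' uniformly shuffling the sample-phenotype assignment (group sizes fixed)
#' and recomputing both graphs and their distance. The p-value includes the
#' observed statistic in the null set, `p = (1 + #{b: stat_b >= stat_obs}) /
#' (1 + B)`, so p is never zero and the test is exact-level.
#'
#' @inheritParams observed_statistic
#' @param B Number of permutations (>= 1). Monte Carlo experiments here use
#'   modest B; for data analysis B = 10000 is a common choice.
#' @param seed Integer seed; the result is fully determined by it.
#' @param set_name Optional name recorded in the result.
#' @return A list of class `coexp_test`: `set_name`, `set_size`,
#'   `statistic_name`, `statistic`, `p_value`, `null` (the B permuted
#'   statistics), `B`, `seed`.
#' @export
permutation_test <- function(expr, labels, gene_set,
                             config = association_config(),
                             kind = "spectral_js", B = 1000L, seed = 1L,
                             criterion = c("sturges", "silverman"),
                             set_name = NA_character_) {
  criterion <- match.arg(criterion)
  stopifnot(B >= 1L)
  ps <- prepare_set(expr, labels, gene_set)
  idx <- split_by_label(ps$labels)
  n1 <- length(idx[[1L]])
  all_idx <- c(idx[[1L]], idx[[2L]])
  obs <- statistic_for_split(ps$x, idx[[1L]], idx[[2L]], config, kind, criterion,
                             warn = TRUE)
  set.seed(seed)
  null <- numeric(B)
  for (b in seq_len(B)) {
    perm <- sample(all_idx)
    null[b] <- statistic_for_split(ps$x, perm[seq_len(n1)], perm[-seq_len(n1)],
                                   config, kind, criterion, warn = FALSE)
  }
  structure(list(set_name = set_name, set_size = length(ps$genes),
                 statistic_name = kind, statistic = obs,
                 p_value = perm_pvalue(obs, null), null = null,
                 B = as.integer(B), seed = as.integer(seed)),
            class = "coexp_test")
}

#' @export
print.coexp_test <- function(x, ...) {
  cat("permutation test of differential co-expression\n")
  if (!is.na(x$set_name)) cat("  set:      ", x$set_name, "\n")
  cat("  size:     ", x$set_size, "\n")
  cat("  statistic:", x$statistic_name, "=", format(x$statistic, digits = 4), "\n")
  cat("  p-value:  ", format(x$p_value, digits = 4), " (", x$B, " permutations)\n", sep = "")
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector, mapped back
#' to the input order.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (q-values) in \[0, 1\].
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Differential co-expression analysis of a gene-set collection
#'
#' Intersects each set with the expression genes, drops sets below
#' `min_size` (sizes are reported post-intersection), runs the permutation
#' test per surviving set with a per-set seed derived from the master seed
#' and the set name (so adding or removing sets does not perturb other sets'
#' p-values), and attaches Benjamini-Hochberg q-values across the surviving
#' sets.
#'
#' @inheritParams permutation_test
#' @param sets A `gene_set_collection` from [read_gmt()], or a named list of
#'   gene symbol vectors.
#' @param min_size Minimum post-intersection set size (default 20; small sets
#'   make network-feature estimates unstable).
#' @return Data frame with columns `set_name`, `set_size`, `statistic_name`,
#'   `statistic`, `p_value`, `q_value`, sorted by increasing p-value.
#' @export
analyze_collection <- function(expr, labels, sets,
                               config = association_config(),
                               kind = "spectral_js", B = 1000L,
                               min_size = 20L, seed = 1L,
                               criterion = c("sturges", "silverman")) {
  criterion <- match.arg(criterion)
  if (length(sets) == 0L) stop("no gene sets supplied")
  sizes <- vapply(sets, function(g) sum(unique(g) %in% rownames(expr)), integer(1L))
  keep <- names(sets)[sizes >= min_size]
  if (length(keep) == 0L)
    stop("no gene set reaches min_size = ", min_size, " after intersection")
  rows <- lapply(keep, function(nm) {
    tst <- permutation_test(expr, labels, sets[[nm]], config, kind, B,
                            seed = derive_seed(seed, nm),
                            criterion = criterion, set_name = nm)
    data.frame(set_name = nm, set_size = tst$set_size,
               statistic_name = tst$statistic_name, statistic = tst$statistic,
               p_value = tst$p_value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- bh_adjust(res$p_value)
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Single-gene differential expression within a gene set
#'
#' Standard per-gene comparisons complementing the network analysis: Welch's
#' two-sample t-test (difference in means) and the two-sided
#' Wilcoxon-Mann-Whitney rank-sum test (difference in medians), reported as
#' nominal p-values. A gene constant in both groups gets p = 1 with a
#' warning.
#'
#' @inheritParams observed_statistic
#' @return Data frame with columns `gene`, `t_p`, `wilcoxon_p`, `mean_diff`
#'   (group 1 mean minus group 2 mean).
#' @export
differential_expression <- function(expr, labels, gene_set) {
  labels <- align_labels(labels, expr)
  genes <- gene_set[gene_set %in% rownames(expr)]
  if (length(genes) == 0L) stop("no gene of the set is present in the expression matrix")
  idx <- split_by_label(labels)
  if (any(lengths(idx) < 2L)) stop("each phenotype needs at least 2 samples")
  res <- lapply(genes, function(g) {
    a <- expr[g, idx[[1L]]]
    b <- expr[g, idx[[2L]]]
    if (stats::var(c(a, b)) == 0) {
      warning("gene ", g, " is constant in both groups; p-values set to 1")
      tp <- 1; wp <- 1
    } else {
      tp <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
      wp <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    }
    data.frame(gene = g, t_p = tp, wilcoxon_p = wp, mean_diff = mean(a) - mean(b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Rank genes by network importance
#'
#' Orders the genes of a co-expression graph by a node score (descending;
#' ties broken alphabetically by gene symbol). Degree, eigenvector and
#' clustering scores apply to any graph; betweenness and closeness require an
#' unweighted graph.
#'
#' @param graph A `coexpression_graph`.
#' @param kind One of `"degree"`, `"eigenvector"`, `"clustering"`,
#'   `"betweenness"`, `"closeness"`.
#' @return Data frame with columns `gene` and `score`, highest first.
#' @export
rank_genes <- function(graph, kind = c("degree", "eigenvector", "clustering",
                                       "betweenness", "closeness")) {
  kind <- match.arg(kind)
  scores <- switch(kind,
    degree = degree_centrality(graph),
    eigenvector = eigenvector_centrality(graph),
    clustering = local_clustering(graph),
    betweenness = path_centrality(graph, "betweenness"),
    closeness = path_centrality(graph, "closeness"))
  ord <- order(-scores, names(scores), method = "radix")
  data.frame(gene = names(scores)[ord], score = unname(scores[ord]),
             stringsAsFactors = FALSE)
}

#' Edge-weight difference matrix between two graphs
#'
#' Elementwise difference of the adjacency matrices of two graphs over the
#' same gene set, for inspection or export of where the co-expression
#' structure changed.
#'
#' @param g1,g2 `coexpression_graph` objects over the same ordered gene set.
#' @return Symmetric numeric matrix `g1 - g2`.
#' @export
edge_difference_matrix <- function(g1, g2) {
  if (!identical(g1$nodes, g2$nodes))
    stop("graphs must share the same ordered node set")
  g1$adjacency - g2$adjacency
}
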