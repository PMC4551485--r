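#' Degree centrality (node strength)
#'
#' For weighted graphs the degree of a node is its strength, the sum of
#' incident edge weights; for unweighted graphs this reduces to the edge
#' count.
#'
#' @param graph A `coexpression_graph`.
#' @return Named numeric vector aligned to node order.
#' @export
degree_centrality <- function(graph) {
  rowSums(graph$adjacency)
}

#' Eigenvector centrality
#'
#' Scores nodes by the principal (Perron) eigenvector of the adjacency
#' matrix: a gene is important when it is strongly connected to other
#' important genes. Entries are nonnegative and normalized to unit L2 norm.
#'
#' @param graph A `coexpression_graph` with at least one edge.
#' @return Named numeric vector of scores.
#' @export
eigenvector_centrality <- function(graph) {
  a <- graph$adjacency
  if (all(a == 0)) stop("eigenvector centrality undefined for an edgeless graph")
  e <- eigen(a, symmetric = TRUE)
  v <- e$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  v[v < 0] <- 0  # clip round-off on the Perron vector
  v <- v / sqrt(sum(v^2))
  stats::setNames(v, graph$nodes)
}

#' Betweenness and closeness centrality
#'
#' Shortest-path centralities, available for unweighted graphs only.
#' Betweenness counts, per node, the shortest paths between other node pairs
#' passing through it (unnormalized); closeness of a node is the number of
#' nodes reachable from it divided by the total distance to them, which on a
#' connected graph is `(n_V - 1) / sum(distances)`. Unreachable nodes are
#' excluded (per-component closeness); isolated nodes score 0.
#'
#' @param graph An unweighted `coexpression_graph` (all weights 0 or 1).
#' @param kind `"betweenness"` or `"closeness"`.
#' @return Named numeric vector of scores.
#' @export
path_centrality <- function(graph, kind = c("betweenness", "closeness")) {
  kind <- match.arg(kind)
  a <- graph$adjacency
  if (!all(a %in% c(0, 1)))
    stop("betweenness/closeness centralities require an unweighted graph")
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  if (kind == "betweenness") {
    scores <- igraph::betweenness(g, directed = FALSE, weights = NA)
  } else {
    d <- igraph::distances(g)
    scores <- apply(d, 1L, function(row) {
      row <- row[is.finite(row) & row > 0]
      if (length(row) == 0L) 0 else length(row) / sum(row)
    })
  }
  stats::setNames(as.numeric(scores), graph$nodes)
}

#' Local clustering coefficient
#'
#' For unweighted graphs, the fraction of a node's neighbour pairs that are
#' themselves connected. For weighted graphs, Onnela's geometric-mean
#' generalization on max-normalized weights:
#' `C_i = sum_{j,k} (w_ij w_jk w_ki / max(w)^3)^(1/3) / (k_i (k_i - 1))`,
#' where `k_i` is the number of neighbours. Nodes with fewer than two
#' neighbours score 0. The unweighted case is the same formula on 0/1
#' weights.
#'
#' @param graph A `coexpression_graph`.
#' @return Named numeric vector in \[0, 1\].
#' @export
local_clustering <- function(graph) {
  a <- graph$adjacency
  n <- nrow(a)
  k <- rowSums(a > 0)
  if (max(a) == 0) return(stats::setNames(numeric(n), graph$nodes))
  w <- (a / max(a))^(1 / 3)
  paths <- diag(w %*% w %*% w)  # closed weighted triangles, both orientations
  c_i <- ifelse(k >= 2, paths / (k * (k - 1)), 0)
  stats::setNames(pmin(pmax(c_i, 0), 1), graph$nodes)
}

#' Average shortest path length
#'
#' Edge lengths are the reciprocal weights 1/w, so strongly associated genes
#' are close; unweighted edges have length 1. The average is taken over
#' reachable ordered pairs only (0 when no pair is reachable), keeping the
#' statistic finite on sparse graphs.
#'
#' @param graph A `coexpression_graph`.
#' @return Nonnegative scalar.
#' @export
average_shortest_path <- function(graph) {
  a <- graph$adjacency
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected", weighted = TRUE)
  wts <- igraph::E(g)$weight
  d <- if (length(wts) == 0L) {
    igraph::distances(g)
  } else {
    igraph::distances(g, weights = 1 / wts)
  }
  vals <- d[row(d) != col(d)]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) 0 else mean(vals)
}

#' Degree distribution as a kernel density
#'
#' Gaussian kernel density of the node strengths, using the same bandwidth
#' machinery as the spectral density, so two graphs' degree distributions can
#' be compared by Jensen-Shannon divergence.
#'
#' @param graph A `coexpression_graph`.
#' @param criterion Bandwidth criterion, see [kde_bandwidth()].
#' @param grid Optional shared evaluation grid.
#' @param n_grid Grid size when `grid` is `NULL`.
#' @return A `spectral_density`-shaped density over degrees.
#' @export
degree_distribution <- function(graph, criterion = c("sturges", "silverman"),
                                grid = NULL, n_grid = 512L) {
  criterion <- match.arg(criterion)
  estimate_density(degree_centrality(graph), criterion, grid, n_grid)
}

#' Graph-distance statistics between two co-expression graphs
#'
#' The nonnegative distance statistics used to test differential
#' co-expression, all zero when the graphs are identical:
#' \describe{
#'   \item{`spectral_js`}{Jensen-Shannon divergence between the spectral
#'     densities evaluated on a shared grid (the default test statistic).}
#'   \item{`degree_dist_js`}{Jensen-Shannon divergence between the degree
#'     distributions.}
#'   \item{`degree_centrality_dist`, `eigenvector_centrality_dist`,
#'     `clustering_dist`}{Euclidean distance between the node score vectors,
#'     divided by the gene-set size so the statistic is a per-gene
#'     discrepancy.}
#'   \item{`shortest_path_absdiff`, `entropy_absdiff`}{Absolute difference of
#'     the average shortest path lengths / the spectral entropies.}
#' }
#'
#' @param g1,g2 `coexpression_graph` objects over the same ordered gene set.
#' @param kind One of the statistic names above.
#' @param criterion Bandwidth criterion for the density-based statistics.
#' @return A nonnegative scalar.
#' @export
graph_distance <- function(g1, g2,
                           kind = c("spectral_js", "degree_dist_js",
                                    "degree_centrality_dist",
                                    "eigenvector_centrality_dist",
                                    "clustering_dist", "shortest_path_absdiff",
                                    "entropy_absdiff"),
                           criterion = c("sturges", "silverman")) {
  kind <- match.arg(kind)
  criterion <- match.arg(criterion)
  if (!identical(g1$nodes, g2$nodes))
    stop("graphs must share the same ordered node set")
  n <- length(g1$nodes)
  switch(kind,
    spectral_js = {
      d <- spectral_densities(g1, g2, criterion)
      js_divergence(d$d1, d$d2)
    },
    degree_dist_js = {
      d <- shared_densities(degree_centrality(g1), degree_centrality(g2), criterion)
      js_divergence(d$d1, d$d2)
    },
    degree_centrality_dist =
      sqrt(sum((degree_centrality(g1) - degree_centrality(g2))^2)) / n,
    eigenvector_centrality_dist =
      sqrt(sum((eigenvector_centrality(g1) - eigenvector_centrality(g2))^2)) / n,
    clustering_dist =
      sqrt(sum((local_clustering(g1) - local_clustering(g2))^2)) / n,
    shortest_path_absdiff =
      abs(average_shortest_path(g1) - average_shortest_path(g2)),
    entropy_absdiff = {
      e1 <- spectral_entropy(spectral_density(adjacency_spectrum(g1), criterion))
      e2 <- spectral_entropy(spectral_density(adjacency_spectrum(g2), criterion))
      abs(e1 - e2)
    })
}

#' Summary properties of a gene-set network
#'
#' Average degree centrality, average eigenvector centrality, average
#' clustering coefficient, spectral entropy, and average shortest path
#' length. The eigenvector average is `NA` for an edgeless graph.
#'
#' @param graph A `coexpression_graph`.
#' @param criterion Bandwidth criterion for the spectral entropy.
#' @return A list of class `gene_set_properties`.
#' @export
set_properties <- function(graph, criterion = c("sturges", "silverman")) {
  criterion <- match.arg(criterion)
  avg_eig <- tryCatch(mean(eigenvector_centrality(graph)),
                      error = function(e) NA_real_)
  structure(list(
    average_degree = mean(degree_centrality(graph)),
    average_eigenvector = avg_eig,
    average_clustering = mean(local_clustering(graph)),
    spectral_entropy = spectral_entropy(
      spectral_density(adjacency_spectrum(graph), criterion)),
    average_shortest_path = average_shortest_path(graph)
  ), class = "gene_set_properties")
}

#' @export
print.gene_set_properties <- function(x, ...) {
  cat(sprintf("average degree:        %.4f\n", x$average_degree))
  cat(sprintf("average eigenvector:   %.4f\n", x$average_eigenvector))
  cat(sprintf("average clustering:    %.4f\n", x$average_clustering))
  cat(sprintf("spectral entropy:      %.4f\n", x$spectral_entropy))
  cat(sprintf("average shortest path: %.4f\n", x$average_shortest_path))
  invisible(x)
}
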