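# Shared fixture builders: everything is generated in code at test time.

# Random symmetric weighted adjacency in [0,1] with zero diagonal.
random_graph <- function(n, seed, density = 0.6) {
  set.seed(seed)
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  w <- stats::runif(sum(ut))
  w[stats::runif(sum(ut)) > density] <- 0
  a[ut] <- w
  a <- a + t(a)
  build_graph(a, association_config())
}

# Unit-weight graph from an edge list (rows: i, j).
graph_from_edges <- function(n, edges, weight = 1) {
  a <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    a[edges[k, 1], edges[k, 2]] <- weight
    a[edges[k, 2], edges[k, 1]] <- weight
  }
  build_graph(a, association_config())
}

complete_graph <- function(n, weight = 1) {
  a <- matrix(weight, n, n)
  diag(a) <- 0
  build_graph(a, association_config())
}

# Small labelled expression fixture: n1 + n2 samples of n_genes iid normals.
toy_expression <- function(n_genes = 10, n1 = 10, n2 = 10, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n_genes * (n1 + n2)), n_genes)
  dimnames(x) <- list(paste0("G", seq_len(n_genes)),
                      paste0("S", seq_len(n1 + n2)))
  labels <- stats::setNames(rep(c("A", "B"), c(n1, n2)), colnames(x))
  list(x = x, labels = labels, genes = rownames(x))
}

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Trapezoid rule written out independently of the package's integrator.
trapz_oracle <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Density object on an explicit grid, bypassing the KDE path.
density_fixture <- function(grid, dens) {
  coexspec:::new_spectral_density(grid, dens / trapz_oracle(grid, dens), 1)
}
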