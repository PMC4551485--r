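#' Adjacency spectrum of a co-expression graph
#'
#' The spectrum of a graph is the multiset of eigenvalues of its adjacency
#' matrix; since the matrix is symmetric with zero diagonal the eigenvalues
#' are real and sum to zero.
#'
#' @param graph A `coexpression_graph`.
#' @return A `graph_spectrum`: list with `eigenvalues` (sorted decreasing) and
#'   `n_v` (vertex count).
#' @export
adjacency_spectrum <- function(graph) {
  a <- graph$adjacency
  n <- nrow(a)
  if (n < 2L) stop("spectrum requires at least 2 vertices")
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  structure(list(eigenvalues = ev, n_v = n), class = "graph_spectrum")
}

#' Kernel bandwidth for spectral and degree densities
#'
#' Sturges' criterion uses the bin width of a Sturges histogram,
#' `h = range / ceiling(log2(n) + 1)`; Silverman's rule of thumb is
#' `h = 0.9 min(sd, IQR/1.34) n^(-1/5)`. A degenerate spread (all values
#' equal) falls back to `1e-3 * max(1, |max value|)` so density estimation
#' never divides by zero.
#'
#' @param values Numeric vector (length >= 2).
#' @param criterion `"sturges"` (default) or `"silverman"`.
#' @return A positive bandwidth.
#' @export
kde_bandwidth <- function(values, criterion = c("sturges", "silverman")) {
  criterion <- match.arg(criterion)
  if (length(values) == 0L) stop("empty input")
  if (length(values) < 2L) stop("bandwidth requires at least 2 values")
  n <- length(values)
  h <- switch(criterion,
    sturges = (max(values) - min(values)) / ceiling(log2(n) + 1),
    silverman = 0.9 * min(stats::sd(values), stats::IQR(values) / 1.34) * n^(-1 / 5)
  )
  if (!is.finite(h) || h <= 0) h <- 1e-3 * max(1, abs(max(values)))
  h
}

# Gaussian mixture density (1/(n h)) sum_j phi((t - v_j)/h) on a grid.
gauss_kde <- function(values, h, grid) {
  rowSums(stats::dnorm(outer(grid, values, "-"), sd = h)) / length(values)
}

new_spectral_density <- function(grid, density, bandwidth) {
  structure(list(grid = grid, density = density, bandwidth = bandwidth),
            class = "spectral_density")
}

#' Spectral density of a graph
#'
#' Estimates the probability density of the graph's eigenvalue distribution
#' by a Gaussian kernel. Eigenvalues are rescaled by 1/n_V beforehand,
#' following the spectral-density definition for graph families; within a
#' two-group comparison the graphs share n_V, so the rescaling shifts both
#' entropies by the same constant and leaves divergences unchanged. The
#' density is renormalized so its trapezoid integral over the grid equals 1.
#'
#' @param spec A `graph_spectrum` from [adjacency_spectrum()].
#' @param criterion Bandwidth criterion, see [kde_bandwidth()].
#' @param grid Optional evaluation grid (strictly increasing). When two
#'   densities are to be compared they must be evaluated on a shared grid.
#' @param n_grid Number of grid points when `grid` is `NULL` (default 512);
#'   the automatic grid spans \[min - 3h, max + 3h\].
#' @return A `spectral_density`: list with `grid`, `density`, `bandwidth`.
#' @export
spectral_density <- function(spec, criterion = c("sturges", "silverman"),
                             grid = NULL, n_grid = 512L) {
  criterion <- match.arg(criterion)
  lam <- spec$eigenvalues / spec$n_v
  estimate_density(lam, criterion, grid, n_grid)
}

# Shared KDE machinery for spectra and degree distributions.
estimate_density <- function(values, criterion, grid = NULL, n_grid = 512L) {
  if (length(values) == 0L) stop("empty spectrum")
  h <- kde_bandwidth(values, criterion)
  if (is.null(grid)) {
    grid <- seq(min(values) - 3 * h, max(values) + 3 * h, length.out = n_grid)
  } else if (any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing")
  }
  dens <- gauss_kde(values, h, grid)
  dens <- dens / pracma::trapz(grid, dens)
  new_spectral_density(grid, dens, h)
}

# Evaluate two value sets on one grid spanning the pooled range extended by
# 3 * max(h1, h2); comparisons (JS, KL) require a common measure.
shared_densities <- function(v1, v2, criterion, n_grid = 512L) {
  h1 <- kde_bandwidth(v1, criterion)
  h2 <- kde_bandwidth(v2, criterion)
  hm <- max(h1, h2)
  grid <- seq(min(v1, v2) - 3 * hm, max(v1, v2) + 3 * hm, length.out = n_grid)
  d1 <- gauss_kde(v1, h1, grid)
  d2 <- gauss_kde(v2, h2, grid)
  list(d1 = new_spectral_density(grid, d1 / pracma::trapz(grid, d1), h1),
       d2 = new_spectral_density(grid, d2 / pracma::trapz(grid, d2), h2))
}

#' Shared-grid spectral densities of two graphs
#'
#' Evaluates the spectral densities of two graphs on one common grid so that
#' divergences between them are well defined.
#'
#' @param g1,g2 `coexpression_graph` objects with the same vertex count.
#' @param criterion Bandwidth criterion.
#' @param n_grid Grid size.
#' @return List with elements `d1` and `d2` (`spectral_density` objects on a
#'   common grid).
#' @export
spectral_densities <- function(g1, g2, criterion = c("sturges", "silverman"),
                               n_grid = 512L) {
  criterion <- match.arg(criterion)
  s1 <- adjacency_spectrum(g1)
  s2 <- adjacency_spectrum(g2)
  shared_densities(s1$eigenvalues / s1$n_v, s2$eigenvalues / s2$n_v,
                   criterion, n_grid)
}

# Floor inside logarithms: preserves 0 log 0 = 0 while avoiding -Inf from
# round-off on renormalized densities.
.density_eps <- 1e-12

#' Spectral entropy
#'
#' Differential entropy `H = -integral rho log rho` of a density by the
#' trapezoid rule on its grid (natural log, `0 log 0 = 0`). Quantifies the
#' structural randomness of the graph; may be negative.
#'
#' @param d A `spectral_density`.
#' @return The entropy in nats.
#' @export
spectral_entropy <- function(d) {
  p <- d$density
  y <- ifelse(p > .density_eps, p * log(p), 0)
  -pracma::trapz(d$grid, y)
}

#' Kullback-Leibler divergence between densities
#'
#' `KL(d1 | d2) = integral rho1 log(rho1 / rho2)` on the shared grid, with
#' `0 log 0 = 0`. If the support of the reference `d2` does not contain the
#' support of `d1` the divergence is `+Inf`.
#'
#' @param d1,d2 `spectral_density` objects on the same grid.
#' @return A nonnegative value, possibly `Inf`.
#' @export
kl_divergence <- function(d1, d2) {
  check_same_grid(d1, d2)
  p <- d1$density
  q <- d2$density
  active <- p > .density_eps
  if (any(active & q == 0)) return(Inf)  # support of d2 does not contain d1's
  y <- numeric(length(p))
  y[active] <- p[active] * log(p[active] / pmax(q[active], .density_eps))
  max(pracma::trapz(d1$grid, y), 0)
}

#' Jensen-Shannon divergence between densities
#'
#' Symmetrized divergence `JS = KL(d1|m)/2 + KL(d2|m)/2` with
#' `m = (d1 + d2)/2`; always finite and bounded by `log 2`. Its square root
#' is a metric on densities, which makes it a usable distance between graphs.
#'
#' @param d1,d2 `spectral_density` objects on the same grid.
#' @return A value in \[0, log 2\].
#' @export
js_divergence <- function(d1, d2) {
  check_same_grid(d1, d2)
  m <- new_spectral_density(d1$grid, (d1$density + d2$density) / 2,
                            (d1$bandwidth + d2$bandwidth) / 2)
  js <- 0.5 * kl_divergence(d1, m) + 0.5 * kl_divergence(d2, m)
  min(max(js, 0), log(2))
}

check_same_grid <- function(d1, d2) {
  if (length(d1$grid) != length(d2$grid) ||
      max(abs(d1$grid - d2$grid)) > 1e-9)
    stop("densities must share the same grid (use spectral_densities())")
  invisible(TRUE)
}
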