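#' Co-expression graph configuration
#'
#' Bundles the choices that define how a gene co-expression graph is built:
#' the correlation method, the scale turning test results into association
#' degrees in \[0, 1\], and whether the graph keeps the degrees as edge
#' weights or thresholds them into an unweighted graph.
#'
#' The default configuration -- weighted graphs with edge weights equal to
#' one minus the Spearman p-value after Benjamini-Hochberg adjustment over
#' the gene pairs of the set -- is the one used throughout the package's
#' simulation experiments.
#'
#' @param method Correlation method: `"spearman"` (default), `"pearson"` or
#'   `"kendall"`.
#' @param scale Association-degree scale: `"one_minus_fdr"` (default, one
#'   minus the BH-adjusted p-value), `"one_minus_p"`, or `"abs_corr"`.
#' @param mode `"weighted"` (default) or `"unweighted"`.
#' @param threshold Association-degree threshold in \[0, 1\]; required exactly
#'   when `mode = "unweighted"`.
#' @return A list of class `association_config`.
#' @export
association_config <- function(method = c("spearman", "pearson", "kendall"),
                               scale = c("one_minus_fdr", "one_minus_p", "abs_corr"),
                               mode = c("weighted", "unweighted"),
                               threshold = NULL) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  mode <- match.arg(mode)
  if (mode == "unweighted") {
    if (is.null(threshold)) stop("unweighted mode requires a threshold")
    if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0 || threshold > 1)
      stop("threshold must be a single value in [0, 1]")
  } else if (!is.null(threshold)) {
    stop("threshold is only meaningful in unweighted mode")
  }
  structure(list(method = method, scale = scale, mode = mode, threshold = threshold),
            class = "association_config")
}

#' Pairwise gene association
#'
#' Computes the matrix of pairwise correlations between gene expression
#' profiles and the corresponding two-sided p-values. Pearson and Spearman
#' p-values use the t approximation on n - 2 degrees of freedom (Spearman
#' correlations are Pearson correlations of average ranks); Kendall is tau-b
#' with the standard normal approximation.
#'
#' Genes with zero variance in the given samples (which label permutations
#' can produce) degrade to zero correlation and p-value 1 against every other
#' gene, with a warning, instead of propagating `NA`.
#'
#' @param x Numeric matrix, genes x samples (at least 2 genes, 3 samples).
#' @param method Correlation method.
#' @param warn Emit the constant-gene warning (internal callers disable it
#'   inside permutation loops).
#' @return List with symmetric matrices `corr` (unit diagonal) and `pval`
#'   (zero diagonal).
#' @export
pairwise_association <- function(x, method = c("spearman", "pearson", "kendall"),
                                 warn = TRUE) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), nrow(x) >= 2L, ncol(x) >= 3L)
  n <- ncol(x)
  const <- rowSums((x - rowMeans(x))^2) == 0
  r <- switch(method,
    spearman = {
      xr <- x
      for (i in seq_len(nrow(x))) xr[i, ] <- rank(x[i, ])
      suppressWarnings(stats::cor(t(xr)))
    },
    pearson = suppressWarnings(stats::cor(t(x))),
    kendall = suppressWarnings(stats::cor(t(x), method = "kendall"))
  )
  r[!is.finite(r)] <- 0
  r[r > 1] <- 1
  r[r < -1] <- -1
  if (method == "kendall") {
    z <- 3 * r * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    a <- abs(r)
    tstat <- a * sqrt((n - 2) / (1 - a^2))  # Inf when |r| = 1 -> p = 0
    p <- 2 * stats::pt(-tstat, df = n - 2)
  }
  p[p > 1] <- 1
  if (any(const)) {
    if (warn)
      warning("constant gene(s), associations set to 0: ",
              paste(utils::head(rownames(x)[const], 5L), collapse = ", "))
    r[const, ] <- 0; r[, const] <- 0
    p[const, ] <- 1; p[, const] <- 1
  }
  diag(r) <- 1
  diag(p) <- 0
  dimnames(r) <- dimnames(p) <- list(rownames(x), rownames(x))
  list(corr = r, pval = p)
}

#' Association degrees from correlations and p-values
#'
#' Maps a correlation/p-value pair onto the \[0, 1\] association-degree scale:
#' the absolute correlation, one minus the p-value, or one minus the
#' Benjamini-Hochberg-adjusted p-value. BH adjustment is applied within the
#' set, over its n(n-1)/2 distinct gene pairs, since each gene-set
#' sub-network is built and permutation-tested independently.
#'
#' @param corr Symmetric correlation matrix.
#' @param pval Symmetric p-value matrix.
#' @param scale `"abs_corr"`, `"one_minus_p"` or `"one_minus_fdr"`.
#' @return Symmetric matrix of association degrees in \[0, 1\] with zero
#'   diagonal.
#' @export
association_degree <- function(corr, pval,
                               scale = c("one_minus_fdr", "one_minus_p", "abs_corr")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(corr), is.matrix(pval), all(dim(corr) == dim(pval)))
  d <- switch(scale,
    abs_corr = abs(corr),
    one_minus_p = 1 - pval,
    one_minus_fdr = {
      ut <- upper.tri(pval)
      q <- stats::p.adjust(pval[ut], method = "BH")
      m <- pval
      m[ut] <- q
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      1 - m
    })
  d[d < 0] <- 0
  d[d > 1] <- 1
  diag(d) <- 0
  d
}

#' Construct a co-expression graph from association degrees
#'
#' In weighted mode the adjacency matrix is the degree matrix itself; in
#' unweighted mode edges are the pairs whose association degree reaches the
#' threshold.
#'
#' @param degrees Symmetric association-degree matrix (zero diagonal).
#' @param config An [association_config()].
#' @return A `coexpression_graph`: list with `nodes` (gene symbols in set
#'   order) and `adjacency` (symmetric, zero diagonal, weights in \[0, 1\]).
#' @export
build_graph <- function(degrees, config = association_config()) {
  stopifnot(is.matrix(degrees), nrow(degrees) == ncol(degrees))
  if (config$mode == "unweighted") {
    a <- (degrees >= config$threshold) * 1
  } else {
    a <- degrees
  }
  diag(a) <- 0
  new_coexpression_graph(a, rownames(degrees))
}

new_coexpression_graph <- function(adjacency, nodes = rownames(adjacency)) {
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(adjacency)))
  stopifnot(nrow(adjacency) == ncol(adjacency), length(nodes) == nrow(adjacency))
  if (max(abs(adjacency - t(adjacency))) > 1e-12) stop("adjacency must be symmetric")
  if (any(adjacency < 0) || any(adjacency > 1)) stop("edge weights must lie in [0, 1]")
  adjacency <- (adjacency + t(adjacency)) / 2  # enforce exact symmetry
  diag(adjacency) <- 0
  dimnames(adjacency) <- list(nodes, nodes)
  structure(list(nodes = nodes, adjacency = adjacency), class = "coexpression_graph")
}

#' @export
print.coexpression_graph <- function(x, ...) {
  cat("co-expression graph:", length(x$nodes), "genes,",
      sum(x$adjacency[upper.tri(x$adjacency)] > 0), "nonzero edges\n")
  invisible(x)
}

#' Build a co-expression graph from expression data
#'
#' Convenience wrapper chaining [pairwise_association()],
#' [association_degree()] and [build_graph()] on one phenotype's samples.
#'
#' @param x Expression matrix restricted to one gene set and one phenotype's
#'   samples (genes x samples).
#' @param config An [association_config()].
#' @param warn Passed to [pairwise_association()].
#' @return A `coexpression_graph`.
#' @export
coexpression_graph <- function(x, config = association_config(), warn = TRUE) {
  assoc <- pairwise_association(x, config$method, warn = warn)
  deg <- association_degree(assoc$corr, assoc$pval, config$scale)
  build_graph(deg, config)
}
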