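#' Configuration for the synthetic expression generator
#'
#' Describes a multivariate-normal expression pool with block-constant
#' correlation: genes inside a block share pairwise correlation
#' `within_block_correlation`, genes in different blocks (and genes outside
#' any block) are independent. The defaults -- 50 genes in 5 blocks of 10 at
#' correlation 0.6, 200 samples, unit noise -- provide the correlated null
#' pool used by the Monte Carlo experiments: enough dependence structure that
#' permuting genes in one group visibly disrupts the co-expression graph.
#'
#' @param n_genes Total number of genes.
#' @param n_samples Number of samples (columns) in the pool.
#' @param block_sizes Integer vector of block sizes; must sum to at most
#'   `n_genes`, remaining genes are independent.
#' @param within_block_correlation Common correlation inside each block, in
#'   \[0, 1).
#' @param noise_sd Marginal standard deviation of every gene.
#' @param seed Integer seed for the generator.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 50L, n_samples = 200L,
                              block_sizes = rep(10L, 5L),
                              within_block_correlation = 0.6,
                              noise_sd = 1, seed = 1L) {
  stopifnot(n_genes >= 2L, n_samples >= 2L,
            sum(block_sizes) <= n_genes,
            within_block_correlation >= 0, within_block_correlation < 1,
            noise_sd > 0)
  structure(list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
                 block_sizes = as.integer(block_sizes),
                 within_block_correlation = within_block_correlation,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a block-correlated synthetic expression matrix
#'
#' Samples from a multivariate normal with the block-constant correlation
#' matrix implied by the configuration, via its Cholesky factor. Fully
#' deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return Numeric matrix (genes x samples) with gene names `g001, g002, ...`
#'   and sample names `s1, s2, ...`.
#' @export
generate_expression <- function(config = simulation_config()) {
  p <- config$n_genes
  cmat <- diag(p)
  at <- 0L
  for (b in config$block_sizes) {
    idx <- at + seq_len(b)
    cmat[idx, idx] <- config$within_block_correlation
    at <- at + b
  }
  diag(cmat) <- 1
  ch <- tryCatch(chol(cmat), error = function(e)
    stop("implied correlation matrix is not positive definite (correlation too close to 1?)"))
  set.seed(config$seed)
  z <- matrix(stats::rnorm(config$n_samples * p), config$n_samples, p)
  x <- t(z %*% ch) * config$noise_sd
  dimnames(x) <- list(sprintf("g%03d", seq_len(p)),
                      paste0("s", seq_len(config$n_samples)))
  x
}

new_experiment_report <- function(alphas, rejection_rates, auc, n_reps, n_perms,
                                  seed, p_values) {
  structure(list(alphas = alphas, rejection_rates = rejection_rates, auc = auc,
                 n_reps = as.integer(n_reps), n_perms = as.integer(n_perms),
                 seed = as.integer(seed), p_values = p_values),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Monte Carlo experiment:", x$n_reps, "replicates,", x$n_perms, "permutations each\n")
  show <- c(0.01, 0.05, 0.1)
  for (a in show) {
    i <- which.min(abs(x$alphas - a))
    cat(sprintf("  rejection rate at alpha = %.2f: %.3f\n", x$alphas[i], x$rejection_rates[i]))
  }
  cat(sprintf("  AUC: %.3f\n", x$auc))
  invisible(x)
}

default_alpha_grid <- function() seq(0.005, 1, by = 0.005)

run_replicates <- function(n_reps, seed, draw_fn) {
  vapply(seq_len(n_reps), function(r) {
    rep_seed <- derive_seed(seed, paste0("rep", r))
    set.seed(rep_seed)
    draw_fn(rep_seed)
  }, numeric(1L))
}

#' False-positive-rate experiment under the null
#'
#' Estimates the type-I error of the differential co-expression test. Each
#' replicate draws two groups of columns (sizes `group_sizes`) at random with
#' replacement from the same pooled expression matrix -- so the null of equal
#' co-expression holds by construction -- together with a random gene set of
#' `set_size` genes, and records the permutation-test p-value. The rejection
#' rate at level alpha is the fraction of replicate p-values at or below
#' alpha; a calibrated test keeps it close to alpha.
#'
#' @param pool Pooled expression matrix, e.g. from [generate_expression()].
#' @param group_sizes Integer pair: resampled sizes of the two groups.
#' @param set_size Number of genes drawn per replicate.
#' @param n_reps Number of replicates.
#' @param n_perms Permutations per test.
#' @param alphas Significance-level grid for the rejection-rate curve.
#' @param kind Graph-distance statistic, see [graph_distance()].
#' @param config An [association_config()].
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return An `experiment_report`: `alphas`, `rejection_rates`, `auc`,
#'   `n_reps`, `n_perms`, `seed`, and the replicate `p_values`.
#' @export
fpr_experiment <- function(pool, group_sizes = c(65L, 30L), set_size = 20L,
                           n_reps = 200L, n_perms = 200L,
                           alphas = default_alpha_grid(),
                           kind = "spectral_js",
                           config = association_config(), seed = 1L) {
  stopifnot(nrow(pool) >= set_size, length(group_sizes) == 2L)
  n1 <- group_sizes[1L]; n2 <- group_sizes[2L]
  pvals <- run_replicates(n_reps, seed, function(rep_seed) {
    cols1 <- sample.int(ncol(pool), n1, replace = TRUE)
    cols2 <- sample.int(ncol(pool), n2, replace = TRUE)
    genes <- sample(rownames(pool), set_size)
    x <- cbind(pool[genes, cols1, drop = FALSE], pool[genes, cols2, drop = FALSE])
    colnames(x) <- c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2)))
    labels <- stats::setNames(rep(c("A", "B"), c(n1, n2)), colnames(x))
    permutation_test(x, labels, genes, config, kind, B = n_perms,
                     seed = derive_seed(rep_seed, "perm"))$p_value
  })
  rates <- vapply(alphas, function(a) mean(pvals <= a), numeric(1L))
  new_experiment_report(alphas, rates, roc_auc(alphas, rates),
                        n_reps, n_perms, seed, pvals)
}

#' Power experiment with partially rewired gene sets
#'
#' Estimates the power of the test against a controlled alternative. Each
#' replicate draws `2 * group_size` columns with replacement from the pool,
#' splits them into two groups, draws a `set_size`-gene set, and destroys the
#' co-expression of a proportion `gamma` of those genes in the second group
#' only, by independently permuting each chosen gene's values across that
#' group's samples. Rejection rates over the alpha grid summarize the
#' empirical power; their trapezoidal area (AUC) is 0.5 under the null and
#' approaches 1 for a powerful test.
#'
#' @inheritParams fpr_experiment
#' @param gamma Proportion of the gene set rewired in group 2, in \[0, 1\];
#'   `ceiling(gamma * set_size)` genes are permuted.
#' @param group_size Samples per group.
#' @return An `experiment_report`.
#' @export
power_experiment <- function(pool, gamma, set_size = 50L, group_size = 40L,
                             n_reps = 200L, n_perms = 200L,
                             alphas = default_alpha_grid(),
                             kind = "spectral_js",
                             config = association_config(), seed = 1L) {
  stopifnot(gamma >= 0, gamma <= 1, nrow(pool) >= set_size)
  n_alter <- ceiling(gamma * set_size)
  pvals <- run_replicates(n_reps, seed, function(rep_seed) {
    cols <- sample.int(ncol(pool), 2L * group_size, replace = TRUE)
    genes <- sample(rownames(pool), set_size)
    x <- pool[genes, cols, drop = FALSE]
    colnames(x) <- paste0("c", seq_len(2L * group_size))
    if (n_alter > 0L) {
      g2 <- group_size + seq_len(group_size)
      alter <- sample(seq_len(set_size), n_alter)
      for (g in alter) x[g, g2] <- x[g, g2][sample.int(group_size)]
    }
    labels <- stats::setNames(rep(c("A", "B"), each = group_size), colnames(x))
    permutation_test(x, labels, genes, config, kind, B = n_perms,
                     seed = derive_seed(rep_seed, "perm"))$p_value
  })
  rates <- vapply(alphas, function(a) mean(pvals <= a), numeric(1L))
  new_experiment_report(alphas, rates, roc_auc(alphas, rates),
                        n_reps, n_perms, seed, pvals)
}

#' Area under the power-versus-alpha ROC curve
#'
#' Trapezoidal integral of the empirical power over the significance level,
#' with the curve anchored at (0, 0) and extended horizontally to alpha = 1
#' if the grid stops short. A diagonal curve (power = alpha, the null)
#' yields 0.5; uniformly high power approaches 1.
#'
#' @param alphas Increasing significance levels in \[0, 1\].
#' @param power Rejection rates aligned to `alphas`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(alphas, power) {
  stopifnot(length(alphas) == length(power))
  if (any(diff(alphas) <= 0)) stop("alphas must be strictly increasing")
  if (any(alphas < 0) || any(alphas > 1)) stop("alphas must lie in [0, 1]")
  x <- c(0, alphas)
  y <- c(0, power)
  if (max(alphas) < 1) {
    x <- c(x, 1)
    y <- c(y, power[length(power)])
  }
  pracma::trapz(x, y)
}
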