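test_that("identical data in both phenotypes gives a zero statistic, label-swap invariant", {
  set.seed(2)
  half <- matrix(rnorm(10 * 8), 10, dimnames = list(paste0("G", 1:10), paste0("S", 1:8)))
  x <- cbind(half, half)
  colnames(x) <- paste0("S", 1:16)
  labels <- setNames(rep(c("A", "B"), each = 8), colnames(x))
  expect_lt(observed_statistic(x, labels, rownames(x), kind = "entropy_absdiff"), 1e-10)
  expect_lt(observed_statistic(x, labels, rownames(x), kind = "spectral_js"), 1e-10)

  fix <- toy_expression(n_genes = 8, n1 = 10, n2 = 12, seed = 4)
  swapped <- setNames(ifelse(fix$labels == "A", "B", "A"), names(fix$labels))
  s1 <- observed_statistic(fix$x, fix$labels, fix$genes)
  s2 <- observed_statistic(fix$x, swapped, fix$genes)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("destroying one group's co-expression increases the observed statistic", {
  pool <- generate_expression(simulation_config(n_genes = 20, n_samples = 40,
                                                block_sizes = rep(10, 2), seed = 6))
  x_null <- cbind(pool[, 1:20], pool[, 1:20])
  colnames(x_null) <- paste0("S", 1:40)
  labels <- setNames(rep(c("A", "B"), each = 20), paste0("S", 1:40))
  set.seed(9)
  x_alt <- x_null
  for (g in 1:20) x_alt[g, 21:40] <- x_alt[g, 21:40][sample.int(20)]
  s_null <- observed_statistic(x_null, labels, rownames(pool))
  s_alt <- observed_statistic(x_alt, labels, rownames(pool))
  expect_gt(s_alt, s_null)
})

test_that("permutation p-values are lattice-valued, seed-deterministic, and match the formula", {
  fix <- toy_expression(n_genes = 6, n1 = 6, n2 = 6, seed = 10)
  t1 <- permutation_test(fix$x, fix$labels, fix$genes, B = 19, seed = 123)
  t2 <- permutation_test(fix$x, fix$labels, fix$genes, B = 19, seed = 123)
  expect_identical(t1$p_value, t2$p_value)
  expect_identical(t1$null, t2$null)

  # p = (1 + #{null >= obs}) / (1 + B), on the lattice k/(B+1)
  expect_equal(t1$p_value, (1 + sum(t1$null >= t1$statistic)) / 20)
  expect_true(t1$p_value %in% (seq_len(20) / 20))
  expect_gte(t1$p_value, 1 / 20)
})

test_that("permutation p-values are invariant under monotone rescaling of the statistic", {
  set.seed(14)
  obs <- runif(1)
  null <- runif(50)
  p <- coexspec:::perm_pvalue(obs, null)
  expect_identical(coexspec:::perm_pvalue(10 * obs, 10 * null), p)
  expect_identical(coexspec:::perm_pvalue(exp(obs), exp(null)), p)
})

test_that("null permutation p-values are close to uniform", {
  # two groups drawn from one pool: rejection rate should track alpha
  pool <- generate_expression(simulation_config(n_genes = 10, n_samples = 60,
                                                block_sizes = c(5, 5), seed = 21))
  pvals <- vapply(1:60, function(r) {
    set.seed(300 + r)
    cols <- sample(60, 24, replace = TRUE)
    x <- pool[, cols]
    colnames(x) <- paste0("S", 1:24)
    labels <- setNames(rep(c("A", "B"), each = 12), colnames(x))
    permutation_test(x, labels, rownames(pool), B = 39, seed = 700 + r)$p_value
  }, numeric(1))
  for (a in c(0.05, 0.1)) {
    se <- sqrt(a * (1 - a) / 60)
    expect_lt(abs(mean(pvals <= a) - a), 3 * se + 1 / 40)
  }
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  # min over the tail of scaled order statistics, mapped back to input order
  bh_oracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    sorted <- p[ord]
    adj <- sapply(seq_len(m), function(i) min(1, min(m * sorted[i:m] / (i:m))))
    out <- numeric(m)
    out[ord] <- adj
    out
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(33)
  for (rep in 1:1000) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("collection analysis filters by size, adjusts across sets, and is reproducible", {
  fix <- toy_expression(n_genes = 40, n1 = 8, n2 = 8, seed = 51)
  sets <- list(big1 = paste0("G", 1:25), small = paste0("G", 1:10),
               big2 = paste0("G", 11:40))
  res <- analyze_collection(fix$x, fix$labels, sets, B = 29, min_size = 20, seed = 77)
  expect_identical(nrow(res), 2L)
  expect_true(all(res$set_name %in% c("big1", "big2")))
  expect_identical(res$q_value, bh_adjust(res$p_value)[order(res$p_value)])
  expect_true(!is.unsorted(res$p_value))

  res2 <- analyze_collection(fix$x, fix$labels, sets, B = 29, min_size = 20, seed = 77)
  expect_identical(res, res2)

  # set sizes are post-intersection: genes absent from the matrix don't count
  sets_extra <- list(aug = c(paste0("G", 1:25), "NOT_A_GENE"))
  res3 <- analyze_collection(fix$x, fix$labels, sets_extra, B = 9, min_size = 20, seed = 1)
  expect_identical(res3$set_size, 25L)

  expect_error(analyze_collection(fix$x, fix$labels, list(tiny = "G1"),
                                  B = 9, min_size = 20, seed = 1), "min_size")
})

test_that("per-set seeds make results independent of the rest of the collection", {
  fix <- toy_expression(n_genes = 45, n1 = 8, n2 = 8, seed = 52)
  sets <- list(s1 = paste0("G", 1:20), s2 = paste0("G", 21:40))
  both <- analyze_collection(fix$x, fix$labels, sets, B = 19, min_size = 20, seed = 5)
  solo <- analyze_collection(fix$x, fix$labels, sets["s1"], B = 19, min_size = 20, seed = 5)
  expect_identical(both$p_value[both$set_name == "s1"], solo$p_value)
})

test_that("single-gene differential expression flags separated groups, guards constants", {
  set.seed(61)
  x <- rbind(G1 = c(rnorm(50), rnorm(50, mean = 5)),
             G2 = rnorm(100),
             G3 = rep(1, 100))
  colnames(x) <- paste0("S", 1:100)
  labels <- setNames(rep(c("A", "B"), each = 50), colnames(x))
  expect_warning(de <- differential_expression(x, labels, c("G1", "G2", "G3")), "G3")
  expect_identical(nrow(de), 3L)
  expect_lt(de$t_p[1], 1e-10)
  expect_lt(de$wilcoxon_p[1], 1e-10)
  expect_equal(de$t_p[3], 1)
  # cross-check against the standard implementations
  expect_equal(de$t_p[2], t.test(x[2, 1:50], x[2, 51:100])$p.value, tolerance = 1e-12)
  expect_equal(de$mean_diff[1], mean(x[1, 1:50]) - mean(x[1, 51:100]), tolerance = 1e-12)
})

test_that("gene rankings order by score with alphabetical tie-breaks", {
  star <- graph_from_edges(4, cbind(1, 2:4))
  star$nodes <- c("HUB", "B", "C", "A")
  dimnames(star$adjacency) <- list(star$nodes, star$nodes)
  rk <- rank_genes(star, "degree")
  expect_identical(rk$gene[1], "HUB")
  expect_identical(rk$gene[-1], c("A", "B", "C"))  # equal scores -> alphabetical
  expect_setequal(rk$gene, star$nodes)
  expect_error(rank_genes(complete_graph(3, 0.5), "betweenness"), "unweighted")
})

test_that("edge difference matrices are antisymmetric in their arguments", {
  g1 <- random_graph(5, seed = 71)
  g2 <- random_graph(5, seed = 72)
  d12 <- edge_difference_matrix(g1, g2)
  expect_equal(d12, -edge_difference_matrix(g2, g1))
  expect_true(all(edge_difference_matrix(g1, g1) == 0))
  # a single differing edge shows up in exactly two symmetric cells
  g3 <- g1
  g3$adjacency[2, 3] <- g3$adjacency[3, 2] <- g1$adjacency[2, 3] / 2 + 0.01
  expect_identical(sum(edge_difference_matrix(g1, g3) != 0), 2L)
})
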