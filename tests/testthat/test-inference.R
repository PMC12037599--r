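test_that("trapezoidal AUC on closed-form curves", {
  grid <- sparsity_grid()
  expect_equal(auc_trapezoid(rep(1, 31), grid), 0.30)          # rectangle
  expect_equal(auc_trapezoid(seq(0, 1, length.out = 31), grid), 0.15)  # triangle
  expect_error(auc_trapezoid(c(1, 2), c(0.2, 0.1)), "increasing")
})

test_that("AUC matches a fine-grid Riemann-sum oracle on a random curve", {
  set.seed(14)
  grid <- sparsity_grid()
  vals <- runif(31)
  # midpoint rule at 10x resolution on the piecewise-linear interpolant
  fine <- seq(0.10, 0.40, length.out = 3001)
  mid <- (fine[-1] + fine[-length(fine)]) / 2
  oracle <- sum(approx(grid, vals, xout = mid)$y * diff(fine))
  expect_equal(auc_trapezoid(vals, grid), oracle, tolerance = 1e-9)
})

test_that("group relabeling preserves sizes, subjects and determinism", {
  co <- small_synthetic(n_per_group = c(50, 49), seed = 10)
  p1 <- permute_groups(co, seed = 5)
  p2 <- permute_groups(co, seed = 5)
  p3 <- permute_groups(co, seed = 6)
  expect_equal(as.vector(table(p1$group)), c(50, 49))
  expect_identical(p1$group, p2$group)
  expect_false(identical(p1$group, p3$group))
  expect_identical(p1$subjects, co$subjects)   # subjects untouched
  expect_identical(p1$values, co$values)
})

test_that("BH adjustment matches the hand-evaluated step-up example", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.037), 0.037)                  # m = 1: unchanged
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))      # equal p's unchanged
  p <- c(0.003, 0.04, 0.8, 0.012, 0.3)
  expect_equal(bh_fdr(rev(p)), rev(bh_fdr(p)))        # order invariance
  # independent step-up oracle: p_(i) * m / i with monotonicity from the top
  m <- length(p)
  o <- order(p)
  stepped <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(pmin(stepped, 1))))
  expect_equal(bh_fdr(p)[o], adj)
})

test_that("permutation test statistic and estimator behave as specified", {
  co <- small_synthetic(n_per_group = c(15, 15), regions = toy_regions(3),
                        n_blocks = 2, seed = 20)
  corrected <- residualize(co)
  grid <- sparsity_grid(0.2, 0.4, 0.1)
  pt <- suppressWarnings(global_permutation_test(
    corrected, "Eglob", grid, repetitions = 199, seed = 3))
  # observed statistic equals a by-hand pipeline re-run
  for (g in c("A", "B")) {
    net <- correlation_matrix(corrected, g)
    vals <- vapply(grid, function(s)
      global_efficiency(binarize_at_sparsity(net, s)), numeric(1))
    expect_equal(unname(pt$observed[[g]]), auc_trapezoid(vals, grid))
  }
  expect_equal(pt$diff, pt$observed[[1]] - pt$observed[[2]])
  # add-one estimator: p in (0, 1], never 0, consistent with the null draws
  expect_equal(pt$p, (1 + sum(abs(pt$null) >= abs(pt$diff))) / 200)
  expect_gt(pt$p, 0)
  expect_length(pt$null, 199)
  # 95% band is the percentile interval and brackets the null median
  expect_equal(pt$band, unname(quantile(pt$null, c(0.025, 0.975))))
  expect_true(pt$band[1] <= median(pt$null) && median(pt$null) <= pt$band[2])
  # bit-for-bit reproducibility of the whole null
  pt2 <- suppressWarnings(global_permutation_test(
    corrected, "Eglob", grid, repetitions = 199, seed = 3))
  expect_identical(pt$null, pt2$null)
  expect_error(global_permutation_test(corrected, "not_a_metric", grid,
                                       repetitions = 199, seed = 1))
})

test_that("observed statistic is invariant to subject row order", {
  co <- small_synthetic(n_per_group = c(12, 12), regions = toy_regions(3),
                        n_blocks = 2, seed = 44)
  corrected <- residualize(co)
  set.seed(9)
  perm <- sample(length(corrected$subjects))
  shuffled <- corrected
  shuffled$subjects <- corrected$subjects[perm]
  shuffled$values <- corrected$values[perm, ]
  shuffled$group <- corrected$group[perm]
  shuffled$age <- corrected$age[perm]
  shuffled$sex <- corrected$sex[perm]
  grid <- sparsity_grid(0.2, 0.4, 0.1)
  for (g in c("A", "B")) {
    n1 <- correlation_matrix(corrected, g)
    n2 <- correlation_matrix(shuffled, g)
    expect_equal(n1$matrix, n2$matrix, tolerance = 1e-12)
  }
})

test_that("p-values are uniform under the null (exchangeability)", {
  # H0 cohorts: both groups from one distribution; reduced scale
  reps <- 60
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    co <- small_synthetic(n_per_group = c(12, 12), regions = toy_regions(3),
                          n_blocks = 2, seed = 400 + r)
    pt <- suppressWarnings(global_permutation_test(
      residualize(co), "Eglob", sparsity_grid(0.2, 0.4, 0.1),
      repetitions = 199, seed = r))
    pvals[r] <- pt$p
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(pvals > 0 & pvals <= 1))
})

test_that("nodal permutation test with FDR is calibrated and well-formed", {
  co <- small_synthetic(n_per_group = c(20, 20), regions = toy_regions(4),
                        n_blocks = 2, seed = 55)
  corrected <- residualize(co)
  res <- nodal_permutation_test_fdr(corrected, "degree", sparsity = 0.3,
                                    repetitions = 199, seed = 2)
  expect_equal(nrow(res), 8)
  expect_equal(res$region, co$regions$id)
  expect_true(all(res$p_raw > 0 & res$p_raw <= 1))
  expect_equal(res$p_bh, bh_fdr(res$p_raw))
  # null-identical groups: no significant regions expected
  expect_equal(sum(res$significant), 0)
})
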