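test_that("binomial ASE p-value matches hand-derived values and symmetry", {
  expect_equal(binomial_ase_p(15, 15), 1)
  expect_equal(binomial_ase_p(0, 30), 2 * 0.5^30, tolerance = 1e-12)
  expect_equal(binomial_ase_p(30, 0), binomial_ase_p(0, 30))
  # vectorised and symmetric under allele swap at a symmetric null
  ref <- c(5, 12, 40, 70, 3)
  alt <- c(25, 12, 60, 30, 97)
  expect_equal(binomial_ase_p(ref, alt), binomial_ase_p(alt, ref))
  expect_true(all(binomial_ase_p(ref, alt) > 0))
  expect_true(all(binomial_ase_p(ref, alt) <= 1))
})

test_that("binomial ASE p-value agrees with stats::binom.test", {
  set.seed(11)
  n <- sample(1:300, 150, replace = TRUE)
  k <- vapply(n, function(nn) sample(0:nn, 1), 0L)
  ours <- binomial_ase_p(k, n - k)
  oracle <- mapply(function(kk, nn) oracle_binom_p(kk, nn - kk), k, n)
  expect_equal(ours, unname(oracle), tolerance = 1e-12)
  # and at an asymmetric null
  ours2 <- binomial_ase_p(k, n - k, null_ratio = 0.3)
  oracle2 <- mapply(function(kk, nn)
    stats::binom.test(kk, nn, p = 0.3)$p.value, k, n)
  expect_equal(ours2, unname(oracle2), tolerance = 1e-12)
})

test_that("double-one-tail convention is a valid alternative", {
  p <- binomial_ase_p(20, 40, method = "double_tail")
  expect_equal(p, min(1, 2 * pbinom(20, 60, 0.5)))
  expect_equal(binomial_ase_p(30, 30, method = "double_tail"), 1)
})

test_that("binomial ASE p-value rejects invalid input", {
  expect_error(binomial_ase_p(0, 0), "must be >= 1")
  expect_error(binomial_ase_p(-1, 5), "non-negative")
  expect_error(binomial_ase_p(2.5, 5), "non-negative integers")
})

test_that("Fisher exact 2x2 matches hand-derived values", {
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5))), 1)
  expect_equal(fisher_exact_2x2(rbind(c(10, 0), c(0, 10))),
               2 / choose(20, 10), tolerance = 1e-12)
  # identical allelic ratios in both conditions give p = 1
  for (ab in list(c(3, 7), c(10, 10), c(1, 9))) {
    expect_equal(fisher_exact_2x2(rbind(ab, ab)), 1)
  }
  # one allele absent in both conditions: single achievable table, p = 1
  expect_equal(fisher_exact_2x2(rbind(c(5, 0), c(7, 0))), 1)
})

test_that("Fisher exact 2x2 is invariant under row/column swap and transpose", {
  set.seed(21)
  for (i in 1:25) {
    tab <- matrix(sample(0:40, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0)) next
    p <- fisher_exact_2x2(tab)
    expect_equal(fisher_exact_2x2(tab[2:1, ]), p)
    expect_equal(fisher_exact_2x2(tab[, 2:1]), p)
    if (all(colSums(tab) > 0)) expect_equal(fisher_exact_2x2(t(tab)), p)
  }
})

test_that("Fisher exact 2x2 agrees with stats::fisher.test", {
  set.seed(31)
  for (i in 1:60) {
    tab <- matrix(rpois(4, lambda = sample(c(5, 30, 120), 1)), 2)
    if (any(rowSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), oracle_fisher_p(tab),
                 tolerance = 1e-9)
  }
})

test_that("Fisher exact 2x2 rejects uninformative tables", {
  expect_error(fisher_exact_2x2(rbind(c(0, 0), c(5, 5))), "row sums")
  expect_error(fisher_exact_2x2(matrix(1:6, 2)), "2x2")
})

test_that("Fisher's method matches the even-df chi-square closed form", {
  r <- fisher_combine(c(1, 1))
  expect_equal(r$chi2, 0)
  expect_equal(r$df, 4L)
  expect_equal(r$p, 1)
  r <- fisher_combine(c(0.05, 0.05))
  expect_equal(r$chi2, -4 * log(0.05), tolerance = 1e-12)
  expect_equal(r$p, exp(-r$chi2 / 2) * (1 + r$chi2 / 2), tolerance = 1e-12)
  # k = 1 is the identity
  expect_equal(fisher_combine(0.37)$p, 0.37, tolerance = 1e-12)
})

test_that("Fisher's method clamps zero p-values and validates input", {
  expect_warning(r <- fisher_combine(c(0, 0.5)), "clamped")
  expect_true(r$p > 0)
  expect_error(fisher_combine(numeric(0)), "non-empty")
  expect_error(fisher_combine(c(0.5, 1.2)), "lie in")
})

test_that("adding an uninformative sample (p = 1) pulls the combination toward 1", {
  for (x in c(1e-6, 0.01, 0.3, 0.9)) {
    expect_lte(fisher_combine(x)$p, fisher_combine(c(x, 1))$p)
  }
})

test_that("BH adjustment matches the hand-computed step-up example", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
})

test_that("BH adjustment is permutation-equivariant and reproduces step-up rejections", {
  set.seed(41)
  for (i in 1:20) {
    p <- runif(sample(5:80, 1))^sample(1:3, 1)
    perm <- sample(seq_along(p))
    expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
    for (alpha in c(0.01, 0.05, 0.2)) {
      expect_identical(which(adjust_bh(p) <= alpha),
                       oracle_bh_reject(p, alpha))
    }
  }
})

test_that("per-observation z-scores invert the exact p-values", {
  expect_equal(snp_effect_z(15, 15), 0)
  p030 <- binomial_ase_p(0, 30)
  expect_equal(snp_effect_z(0, 30),
               qnorm(p030 / 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_gt(snp_effect_z(0, 30), 5.9)  # strong monoallelic signal
  expect_equal(snp_effect_z(table = rbind(c(5, 5), c(5, 5))), 0)
  # the floor keeps z finite for astronomically small p
  expect_true(is.finite(snp_effect_z(0, 5000)))
})

test_that("the Stouffer gene statistic follows its closed form", {
  expect_equal(gene_statistic(c(0, 0, 0)), 0)
  expect_equal(gene_statistic(c(2, 2)), 4 / sqrt(2), tolerance = 1e-12)
  expect_equal(gene_statistic(3.1, weights = 7), 3.1)  # any single weight
  expect_error(gene_statistic(c(1, 2), weights = c(0, 0)), "zero")
  # monotone in each z
  expect_gt(gene_statistic(c(2.5, 1), weights = c(1, 2)),
            gene_statistic(c(2, 1), weights = c(1, 2)))
})
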