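test_that("pooled t-test matches hand computation and conventions", {
  # a=(1,2,3,4), b=(2,3,4,5): pooled variance 5/3, SE = sqrt(5/6), df = 6,
  # t = -1/sqrt(5/6) = -1.0954, p = 0.3153 (cross-checked against an
  # independent pooled t implementation)
  res <- twoSampleTTest(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(res$statistic, -1.0954451, tolerance = 1e-6)
  expect_equal(res$p_value, 0.3153336, tolerance = 1e-6)
  expect_equal(twoSampleTTest(c(1, 2, 3), c(1, 2, 3))$p_value, 1, tolerance = 1e-9)
  # +10 shift at n=3 per group: df = 4, p = 2.55e-4
  expect_lt(twoSampleTTest(c(1, 2, 3), c(11, 12, 13))$p_value, 1e-3)
  # zero-variance conventions
  expect_equal(twoSampleTTest(c(2, 2), c(2, 2))$p_value, 1)
  expect_equal(twoSampleTTest(c(2, 2), c(3, 3))$p_value, 0)
  expect_error(twoSampleTTest(1, c(1, 2)), "n >= 2")
})

test_that("t-test p is invariant to swapping the groups, Welch included", {
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), sd = 2)
    expect_equal(twoSampleTTest(a, b)$p_value, twoSampleTTest(b, a)$p_value)
    expect_equal(twoSampleTTest(a, b, var_equal = FALSE)$p_value,
                 twoSampleTTest(b, a, var_equal = FALSE)$p_value)
  }
})

test_that("log2 fold change follows the disease-minus-control convention", {
  expect_equal(log2FoldChange(c(5, 5), c(4, 4)), 1)
  expect_equal(log2FoldChange(c(3, 3), c(3, 3)), 0)
  # a protein higher in the control group has a negative fold change
  expect_equal(log2FoldChange(c(3.8, 3.8), c(4.05, 4.05)), -0.25)
  expect_error(log2FoldChange(numeric(0), 1), "empty")
})

test_that("BH adjustment matches the hand example and brute-force reference", {
  expect_equal(bhAdjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))
    expect_equal(bhAdjust(p), bruteBH(p), tolerance = 1e-12)
  }
})

test_that("BH adjustment is permutation-equivariant", {
  set.seed(3)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
})

test_that("volcano table flags a planted feature and behaves under the null", {
  sim <- generateDataset(smallSimConfig(seed = 13, effect_size = 0))
  m <- log2Transform(sim$quant)
  v <- quantValues(m)
  v["P00001", sim$samples$group == "TypeB"] <-
    v["P00001", sim$samples$group == "TypeB"] + 5
  m <- QuantMatrix(v, scale = "log2")
  vt <- volcanoTable(m, sim$samples, case = "TypeB")
  planted <- vt[vt$feature_id == "P00001", ]
  expect_true(planted$significant)
  expect_gt(planted$log2fc, 0)
  expect_true(all(vt$p_adj >= vt$p_raw - 1e-12))
  expect_equal(vt$neg_log10_p_adj, -log10(vt$p_adj))
  # null data: BH controls the FDR, so significant calls are rare
  n_sig <- sapply(1:20, function(s) {
    simn <- generateDataset(smallSimConfig(seed = 100 + s, effect_size = 0))
    vtn <- volcanoTable(log2Transform(simn$quant), simn$samples,
                        case = "TypeB")
    sum(vtn$significant)
  })
  expect_gte(sum(n_sig == 0), 18)
})

test_that("volcano table handles the empty feature set", {
  sim <- generateDataset(smallSimConfig(seed = 1))
  m <- log2Transform(sim$quant)
  empty <- QuantMatrix(quantValues(m)[0, , drop = FALSE], scale = "log2")
  vt <- volcanoTable(empty, sim$samples, case = "TypeB")
  expect_identical(nrow(vt), 0L)
})

test_that("2x2 Fisher test matches enumeration and the reference", {
  expect_equal(fisherExact2x2(matrix(c(1, 1, 1, 1), 2, 2)), 1)
  # [[5,0],[0,5]]: only the two extreme tables fall in the tail
  expect_equal(fisherExact2x2(matrix(c(5, 0, 0, 5), 2, 2)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisherExact2x2(matrix(c(3, 0, 0, 0), 2, 2)), 1)
  expect_error(fisherExact2x2(matrix(c(-1, 1, 1, 1), 2, 2)), "non-negative")
  set.seed(11)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2, 2)
    expect_equal(fisherExact2x2(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("Freeman-Halton equals the 2x2 test and the reference on r x 2", {
  set.seed(21)
  for (i in 1:200) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2, 2)
    if (all(colSums(tab) > 0))
      expect_equal(fisherFreemanHalton(tab), fisherExact2x2(tab),
                   tolerance = 1e-12)
  }
  for (i in 1:20) {
    tab <- matrix(rpois(8, 5), 4, 2)
    if (all(colSums(tab) > 0))
      expect_equal(fisherFreemanHalton(tab),
                   fisher.test(tab, workspace = 2e7)$p.value,
                   tolerance = 1e-6)
  }
})

test_that("Freeman-Halton handles zero rows, bounds and the Monte Carlo path", {
  tab <- matrix(c(5, 0, 2, 7, 0, 3), 3, 2)
  expect_equal(fisherFreemanHalton(tab),
               fisherFreemanHalton(tab[c(1, 3), ]), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 6), 3, 2)
    if (all(colSums(tab) > 0)) {
      p <- fisherFreemanHalton(tab)
      expect_gt(p, 0); expect_lte(p, 1)
    }
  }
  # identical column proportions -> p = 1
  expect_equal(fisherFreemanHalton(matrix(c(4, 6, 4, 6), 2, 2)), 1)
  big <- matrix(c(40, 35, 30, 42, 33, 31), 3, 2)
  expect_error(fisherFreemanHalton(big, max_tables = 10), "monte_carlo")
  p_mc <- fisherFreemanHalton(big, max_tables = 10, monte_carlo = TRUE,
                              mc_samples = 2e4, seed = 1)
  expect_equal(p_mc, fisherFreemanHalton(big), tolerance = 0.02)
})

test_that("cohort contingency tables reproduce their printed p-values", {
  sex <- matrix(c(46, 29, 36, 26), 2, 2)
  expect_equal(round(fisherExact2x2(sex), 2), 0.73)
  eth <- matrix(c(37, 24, 13, 1, 0, 41, 12, 7, 0, 2), ncol = 2)
  expect_equal(round(fisherFreemanHalton(eth), 2), 0.07)
})

test_that("Wilcoxon rank-sum: exact enumeration, ties, and null calibration", {
  # a=(1,2), b=(3,4): most extreme of the C(4,2)=6 assignments, two-sided
  expect_equal(wilcoxonRankSum(c(1, 2), c(3, 4)), 2 / 6, tolerance = 1e-12)
  expect_gt(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3)), 0.99)
  expect_error(wilcoxonRankSum(numeric(0), 1), "empty")
  set.seed(9)
  ps <- replicate(1000, wilcoxonRankSum(rnorm(20), rnorm(20)))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("train-only filter selects planted features and respects alpha", {
  hits <- sapply(1:10, function(s) {
    sim <- generateDataset(smallSimConfig(seed = 200 + s, effect_size = 0))
    m <- log2Transform(sim$quant)
    v <- quantValues(m)
    v["P00001", sim$samples$group == "TypeB"] <-
      v["P00001", sim$samples$group == "TypeB"] + 4
    m <- QuantMatrix(v, scale = "log2")
    sel <- trainOnlyStatFilter(m, sim$samples, alpha = 0.01, case = "TypeB")
    identical(sel, "P00001")
  })
  expect_gte(sum(hits), 9)
  sim <- generateDataset(smallSimConfig(seed = 1))
  m <- log2Transform(sim$quant)
  expect_identical(trainOnlyStatFilter(m, sim$samples, alpha = 1),
                   featureIds(m))
  expect_error(trainOnlyStatFilter(m, sim$samples, alpha = 0), "alpha")
  # null data: selection usually empty
  empties <- sapply(1:20, function(s) {
    simn <- generateDataset(smallSimConfig(seed = 300 + s, effect_size = 0))
    length(trainOnlyStatFilter(log2Transform(simn$quant), simn$samples,
                               alpha = 0.01)) == 0
  })
  expect_gte(sum(empties), 18)
})
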