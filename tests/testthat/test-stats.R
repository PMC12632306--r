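test_that("exact 2x2 Fisher matches enumeration oracles", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 2, 2, 2), 2))$p.value, 1.0)
  # frozen from full hypergeometric enumeration (and stats::fisher.test)
  expect_equal(fisher_exact_2x2(matrix(c(7, 1, 2, 12), 2,
                                       byrow = TRUE))$p.value,
               0.001491697, tolerance = 1e-6)
  expect_equal(fisher_exact_2x2(matrix(c(0, 8, 3, 11), 2,
                                       byrow = TRUE))$p.value,
               0.2727273, tolerance = 1e-6)
  # independent oracle on random tables
  withr::with_seed(201, for (i in 1:25) {
    tab <- matrix(stats::rpois(4, 6), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab)$p.value,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  })
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)),
               "non-negative")
  # the doubled-one-tail convention is available and differs in general
  p_mass <- fisher_exact_2x2(matrix(c(0, 8, 3, 11), 2, byrow = TRUE))
  p_dbl <- fisher_exact_2x2(matrix(c(0, 8, 3, 11), 2, byrow = TRUE),
                            alternative = "doubled")
  expect_true(p_dbl$p.value >= p_mass$p.value - 1e-12)
})

test_that("hypergeometric table probabilities sum to one", {
  withr::with_seed(202, for (i in 1:1000) {
    m <- sample(0:30, 1); n <- sample(0:30, 1); k <- sample(0:(m + n), 1)
    x <- max(0, k - n):min(k, m)
    expect_equal(sum(stats::dhyper(x, m, n, k)), 1, tolerance = 1e-12)
  })
})

test_that("fixed-margin table sampler preserves margins and the null", {
  rm <- c(8, 7, 7); cm <- c(3, 10, 9)
  s <- withr::with_seed(203, sample_fixed_margin_tables(500, rm, cm))
  for (i in 1:3) expect_true(all(rowSums(s[, (i - 1) * 3 + 1:3]) == rm[i]))
  for (j in 1:3) expect_true(all(s[, j] + s[, j + 3] + s[, j + 6] == cm[j]))
  # cell means match the margin-expected table
  expected <- outer(rm, cm) / sum(rm)
  expect_equal(colMeans(s), as.vector(t(expected)), tolerance = 0.15)
})

test_that("Monte Carlo Fisher agrees with exact enumeration on 2x2 tables", {
  tab <- matrix(c(7, 1, 2, 12), 2, byrow = TRUE)
  pe <- fisher_exact_2x2(tab)$p.value
  pm <- fisher_montecarlo(tab, B = 10000, seed = 3)$p.value
  expect_lt(abs(pm - pe), 3 * sqrt(pe * (1 - pe) / 10000) + 1 / 10001)
  # p-hat converges: absolute error within 3 SE at each B
  for (B in c(1000, 10000, 100000)) {
    p <- fisher_montecarlo(tab, B = B, seed = 11)$p.value
    expect_lt(abs(p - pe), 3 * sqrt(pe * (1 - pe) / B) + 1 / (B + 1))
  }
  # the margin-expected table is as probable as it gets
  even <- matrix(c(5, 5, 5, 5), 2)
  expect_gt(fisher_montecarlo(even, B = 2000, seed = 5)$p.value, 0.9)
  expect_error(fisher_montecarlo(tab, B = 10), "B must")
  expect_warning(fisher_montecarlo(rbind(tab, c(0, 0)), B = 1000, seed = 1),
                 "all-zero")
})

test_that("Monte Carlo Fisher p-values are uniform under the null", {
  pv <- withr::with_seed(205, vapply(1:300, function(i) {
    tab <- t(vapply(1:3, function(r)
      as.vector(stats::rmultinom(1, 40, rep(1 / 3, 3))), double(3)))
    fisher_montecarlo(tab, B = 1999, seed = i)$p.value
  }, double(1)))
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("Kruskal-Wallis H matches hand computation and base R", {
  kw <- kruskal_wallis_bonferroni(list(1:3, 4:6, 7:9))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2)
  # oracle: base R on random data with ties
  withr::with_seed(206, for (i in 1:20) {
    g <- lapply(1:3, function(j) sample(1:8, sample(4:9, 1), TRUE))
    ours <- kruskal_wallis_bonferroni(g)
    base <- stats::kruskal.test(g)
    expect_equal(ours$statistic, unname(base$statistic), tolerance = 1e-12)
    expect_equal(ours$p.value, base$p.value, tolerance = 1e-12)
  })
  # all-tied groups are flagged instead of dividing by zero
  tied <- kruskal_wallis_bonferroni(list(c(2, 2), c(2, 2, 2)))
  expect_true(tied$all_ties)
  expect_equal(tied$statistic, 0)
  expect_error(kruskal_wallis_bonferroni(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis_bonferroni(list(1:3, numeric(0))),
               "at least one")
})

test_that("Bonferroni correction multiplies and caps pairwise p-values", {
  expect_equal(bonferroni(0.012, 3), 0.036)
  expect_equal(bonferroni(0.5, 4), 1)
  kw <- kruskal_wallis_bonferroni(list(1:5, 3:8, 10:15), pairwise = TRUE)
  expect_equal(nrow(kw$pairwise), 3)
  expect_equal(kw$pairwise$p_adjusted,
               pmin(1, 3 * kw$pairwise$p), tolerance = 1e-12)
})
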