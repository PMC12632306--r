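test_that("lineage tree bookkeeping: structure, de novo load, zero-rate case", {
  p <- sim_params(n_generations = 6, denovo_count = 10)
  tr <- simulate_lineage(p, seed = 1)
  cat <- tr$catalog
  expect_equal(sum(cat$origin_class == "denovo"), 10)
  expect_true(all(cat$origin_node[cat$origin_class == "denovo"] == 1))
  expect_true(all(cat$origin_node[cat$origin_class == "eem"] > 1))
  expect_false(any(duplicated(paste(cat$chrom, cat$pos))))
  # de novo variants reach every terminal cell; every EEM a strict subset
  leaves <- twinEEM:::generation_nodes(6)
  cf <- twinEEM:::carrier_fraction(tr, leaves)
  expect_true(all(cf[cat$origin_class == "denovo"] == 1))
  expect_true(all(cf[cat$origin_class == "eem"] < 1))
  expect_true(all(cf[cat$origin_class == "eem"] > 0))
  # zero mutation rate: only de novo variants exist
  tr0 <- simulate_lineage(sim_params(mutation_rate = 0, n_generations = 5),
                          seed = 2)
  expect_equal(nrow(tr0$catalog), tr0$catalog$mut_id[nrow(tr0$catalog)])
  expect_true(all(tr0$catalog$origin_class == "denovo"))
  expect_error(sim_params(n_generations = 0), "n_generations")
})

test_that("same seed reproduces the simulation bit-identically", {
  a <- simulate_lineage(sim_params(n_generations = 7), seed = 99)
  b <- simulate_lineage(sim_params(n_generations = 7), seed = 99)
  expect_identical(a, b)
  ca <- simulate_cohort(small_config(), seed = 5)
  cb <- simulate_cohort(small_config(), seed = 5)
  expect_identical(ca$metadata, cb$metadata)
  expect_identical(lapply(ca$families, `[[`, "table"),
                   lapply(cb$families, `[[`, "table"))
})

test_that("EEM accrual follows the Poisson clock", {
  # Monte Carlo: mean total EEM count over replicates vs mu * n_nonroot
  mu <- 1.2; G <- 10; n_nonroot <- 2^(G + 1) - 2
  tot <- withr::with_seed(11, vapply(1:500, function(i)
    sum(stats::rpois(n_nonroot, mu)), double(1)))
  # oracle above; implementation below, on fewer replicates
  sims <- vapply(1:60, function(i)
    sum(simulate_lineage(sim_params(mutation_rate = mu, n_generations = G),
                         seed = 1000 + i)$catalog$origin_class == "eem"),
    double(1))
  expected <- mu * n_nonroot
  se <- stats::sd(tot) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - expected), 3 * se * sqrt(500 / 60))
  # per-node counts fit Poisson(mu): chi-square GOF on >= 10,000 nodes
  tr <- simulate_lineage(sim_params(mutation_rate = mu, n_generations = 13),
                         seed = 21)
  counts <- tabulate(tr$mut_node[tr$catalog$origin_class == "eem"],
                     nbins = 2^14 - 1)[-1]
  k <- 0:6
  obs <- c(vapply(k, function(x) sum(counts == x), double(1)),
           sum(counts > 6))
  pr <- c(stats::dpois(k, mu), stats::ppois(6, mu, lower.tail = FALSE))
  chi <- sum((obs - length(counts) * pr)^2 / (length(counts) * pr))
  expect_gt(stats::pchisq(chi, length(obs) - 1, lower.tail = FALSE), 0.01)
})

test_that("twinning partitions conserve cells and honour the three modes", {
  tr <- simulate_lineage(sim_params(n_generations = 9), seed = 3)
  # para: complete segregation of the two daughter lineages
  pp <- apply_twinning(tr, "para", 1, seed = 4)
  expect_equal(as.numeric(sort(unlist(pp$founders))), c(2, 3))
  expect_equal(c(pp$true_a, pp$true_b), c(1, 0))
  l1 <- twinEEM:::twin_leaves(tr, pp, "twin1")
  l2 <- twinEEM:::twin_leaves(tr, pp, "twin2")
  expect_length(intersect(l1, l2), 0)
  eem <- tr$catalog$origin_class == "eem"
  in1 <- twinEEM:::carrier_fraction(tr, l1)[eem] > 0
  in2 <- twinEEM:::carrier_fraction(tr, l2)[eem] > 0
  expect_false(any(in1 & in2))   # private mutation sets are disjoint
  # sub: Twin 1 buds from one cell; its post-split EEMs are absent in Twin 2
  ps <- apply_twinning(tr, "sub", 5, seed = 5)
  expect_equal(length(ps$founders$twin1) + length(ps$founders$twin2), 2^5)
  expect_equal(ps$true_a, 1)
  expect_true(ps$true_b > 0 && ps$true_b < 1)
  f1 <- ps$founders$twin1
  under_f1 <- tr$catalog$origin_node >= f1 &
    tr$catalog$origin_node <= f1  # the founder itself
  sub_muts <- which(tr$catalog$origin_node == f1)
  if (length(sub_muts)) {
    cf2 <- twinEEM:::carrier_fraction(
      tr, twinEEM:::twin_leaves(tr, ps, "twin2"))
    expect_true(all(cf2[sub_muts] == 0))
  }
  # full: random allocation keeps contributions balanced on average;
  # exact oracle: |a - b| = |2x - 32| / 32 with x hypergeometric
  # (32 of the 64 generation-6 cells drawn into Twin 1, 32 under L1)
  diffs <- vapply(1:200, function(i) {
    pf <- apply_twinning(tr, "full", 6, allocation = 0.5, seed = 100 + i)
    pf$true_a - pf$true_b
  }, double(1))
  x <- 0:32
  oracle <- sum(stats::dhyper(x, 32, 32, 32) * abs(2 * x - 32) / 32)
  expect_equal(mean(abs(diffs)), oracle, tolerance = 0.15)
  expect_lt(mean(abs(diffs)), 0.12)
  expect_error(apply_twinning(tr, "full", 5, allocation = 1.2), "allocation")
})
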