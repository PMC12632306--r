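test_that("tissue sampling yields the model's true VAFs", {
  tr <- simulate_lineage(sim_params(n_generations = 8), seed = 7)
  part <- apply_twinning(tr, "sub", 4, seed = 8)
  ts <- sample_tissue(tr, part, "twin1", "buccal", 64, seed = 9)
  dn <- tr$catalog$origin_class == "denovo"
  expect_true(all(ts$true_vaf[dn] == 0.5))            # heterozygous everywhere
  expect_true(all(ts$true_vaf >= 0 & ts$true_vaf <= 0.5))
  expect_error(sample_tissue(tr, part, "twin1", "liver", 8), "tissue")
  expect_error(sample_tissue(tr, part, "twin3", "buccal", 8), "twin")
})

test_that("read sampling: Poisson depth, binomial alt counts, error floor", {
  p <- sim_params(seq_error = 0.001)
  fake <- list(true_vaf = rep(0, 4000))     # EEM carried by no progenitor
  cnt <- with(list(), sequence_sample(fake, p, "wgs", seed = 10))
  expect_equal(mean(cnt$depth), p$wgs_depth, tolerance = 0.05)
  # expected alt reads = depth * e / 3 when true VAF is 0
  expect_equal(mean(cnt$alt), p$wgs_depth * p$seq_error / 3,
               tolerance = 0.5)
  expect_true(all(is.na(cnt$vaf[cnt$depth == 0])))
})

test_that("observed de novo VAFs centre on 0.5 at whole-genome depth", {
  p <- sim_params()
  fake <- list(true_vaf = rep(0.5, 68 * 22 * 2))
  cnt <- sequence_sample(fake, p, "wgs", seed = 12)
  expect_equal(stats::median(cnt$vaf, na.rm = TRUE), 0.5, tolerance = 0.01)
})

test_that("cord-blood mixing is a linear mixture and respects chorionicity", {
  b1 <- structure(list(sample_id = "T1_cord_blood", individual = "T1",
                       tissue = "cord_blood", progenitors = 1:4,
                       cell_fraction = c(1, 0, 0.5),
                       true_vaf = c(0.5, 0, 0.25)), class = "tissue_sample")
  b2 <- b1; b2$cell_fraction <- c(0, 1, 0.5); b2$true_vaf <- c(0, 0.5, 0.25)
  # dichorionic: identity, no EEM crosses over
  di <- mix_cord_blood(b1, b2, 0.7, "dichorionic")
  expect_identical(di[[1]], b1)
  expect_identical(di[[2]], b2)
  # f = 1: both samples equal Twin 1's unmixed composition
  m1 <- mix_cord_blood(b1, b2, 1, "monochorionic")
  expect_equal(m1[[1]]$cell_fraction, b1$cell_fraction)
  expect_equal(m1[[2]]$cell_fraction, b1$cell_fraction)
  # f = 0.7: Twin-1-unique clonal EEM -> fraction 0.7, VAF 0.35 in both
  m7 <- mix_cord_blood(b1, b2, 0.7, "monochorionic")
  for (k in 1:2) {
    expect_equal(m7[[k]]$cell_fraction[1], 0.7)
    expect_equal(m7[[k]]$true_vaf[1], 0.35)
    expect_equal(m7[[k]]$cell_fraction, 0.7 * b1$cell_fraction +
                   0.3 * b2$cell_fraction)
  }
  expect_error(mix_cord_blood(b1, b2, 1.4, "monochorionic"), "f must")
})

test_that("anchor/counter geometry: midpoint fixed at (0.25, 0.25)", {
  withr::with_seed(31, for (i in 1:100) {
    a <- stats::runif(1); b <- stats::runif(1, 0, a)
    ev <- model_expected_vafs(a, b)
    expect_equal(ev$midpoint, c(0.25, 0.25))
    # conservation: L1 + L2 account for the full soma of each twin
    expect_equal(2 * ev$anchor + 2 * ev$counter, c(1, 1))
  })
})

test_that("single-cell observation model is a proper conditional distribution", {
  sc <- sc_params(0.23, 0.46, 0.01)
  for (g in 0:1) {
    tot <- observation_likelihood(NA, g, sc) +
      observation_likelihood(0L, g, sc) + observation_likelihood(1L, g, sc)
    expect_equal(tot, 1)
  }
  expect_equal(observation_likelihood(NA, 1L, sc), 0.46)
  expect_equal(observation_likelihood(1L, 1L, sc), (1 - 0.46) * (1 - 0.23))
  expect_equal(observation_likelihood(1L, 1L, sc), 0.4158)
  expect_equal(observation_likelihood(1L, 0L, sc_params(fp_rate = 0)), 0)
  expect_error(sc_params(ado_rate = 1.2), "rates")
})

test_that("simulated single cells honour the dropout rates", {
  tr <- simulate_lineage(sim_params(n_generations = 8), seed = 13)
  part <- apply_twinning(tr, "para", 1, seed = 14)
  ts <- sample_tissue(tr, part, "twin1", "pbmc", 64, seed = 15)
  # no noise: observed matrix equals the true genotypes
  m0 <- simulate_single_cells(tr, ts, sc_params(0, 0, 0, 50), seed = 16)
  expect_true(all(m0 == attr(m0, "true_genotype")))
  expect_false(anyNA(m0))
  # default rates: informative fraction ~ 1 - lambda
  m1 <- simulate_single_cells(tr, ts, sc_params(0.23, 0.46, 0.01, 200),
                              variants = 1:400, seed = 17)
  expect_equal(mean(!is.na(m1)), 1 - 0.46, tolerance = 0.01)
  # true-alt detection probability = (1 - lambda)(1 - alpha)
  truth <- attr(m1, "true_genotype")
  det <- mean(m1[truth == 1] == 1, na.rm = FALSE)
  expect_equal(sum(m1 == 1 & truth == 1, na.rm = TRUE) / sum(truth == 1),
               (1 - 0.46) * (1 - 0.23), tolerance = 0.02)
})
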