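test_that("informative EEMs are clonal in exactly one twin", {
  samples <- c("T1_buccal", "T2_buccal")
  d <- rbind(
    data.frame(family = "F", variant = "a", sample = samples, depth = 100,
               alt = c(49, 0)),        # clonal in Twin 1 only
    data.frame(family = "F", variant = "b", sample = samples, depth = 100,
               alt = c(30, 25)),       # subclonal in both: excluded
    data.frame(family = "F", variant = "c", sample = samples, depth = 100,
               alt = c(1, 45)))        # clonal in Twin 2 only
  tab <- variant_table(d)
  calls <- data.frame(variant = c("a", "b", "c"), class = "eem",
                      n_detected = 1, shared = FALSE)
  class(calls) <- c("variant_calls", "data.frame")
  inf <- select_informative(tab, calls, samples)
  expect_equal(inf$variant, c("a", "c"))
  expect_equal(inf$source_twin, c(1, 2))
})

test_that("noise-free mixing recovery is exact to grid resolution", {
  for (m in c(0.2, 0.44, 0.7)) {
    depth <- 20000
    src <- rep(1:2, c(3, 3))
    ev <- ifelse(src == 2, m / 2, (1 - m) / 2)
    d <- data.frame(family = "F", variant = paste0("v", 1:6),
                    sample = "cord1", depth = depth,
                    alt = round(depth * ev))
    est <- estimate_mixing(data.frame(variant = paste0("v", 1:6),
                                      source_twin = src),
                           variant_table(d), "cord1")
    expect_equal(est$estimates$m, m, tolerance = 2e-3)
    expect_true(est$estimates$ci_lo <= est$estimates$m &&
                  est$estimates$m <= est$estimates$ci_hi)
  }
  # Twin-1-unique clonal EEM at blood VAF 0.35 -> Twin-1 fraction 0.70
  d <- data.frame(family = "F", variant = "v1", sample = "cord1",
                  depth = 10000, alt = 3500)
  est <- estimate_mixing(data.frame(variant = "v1", source_twin = 1),
                         variant_table(d), "cord1")
  expect_equal(1 - est$estimates$m, 0.70, tolerance = 2e-3)
})

test_that("zero informative EEMs is an explicit undefined status", {
  est <- estimate_mixing(data.frame(variant = character(0),
                                    source_twin = integer(0)),
                         NULL, "cord1")
  expect_equal(est$status, "undefined")
})

test_that("the binomial mixing likelihood is unimodal; grid and refine agree", {
  withr::with_seed(91, for (i in 1:20) {
    m <- stats::runif(1)
    sim <- simulate_mixing_counts(m, 3, 3, seed = i)
    dp <- vaf_matrix(sim$counts, "depth")[, "cord1"]
    ad <- vaf_matrix(sim$counts, "alt")[, "cord1"]
    grid <- seq(0, 1, by = 1e-3)
    ll <- vapply(grid, twinEEM:::.mix_loglik, double(1), ad, dp,
                 sim$informative$source_twin, 0.001 / 3)
    # count strict local maxima of the profile
    d <- diff(ll)
    n_max <- sum(diff(sign(d)) < 0)
    expect_lte(n_max, 1)
    est <- estimate_mixing(sim$informative, sim$counts, "cord1")
    expect_lt(abs(est$estimates$m - grid[which.max(ll)]), 1e-3 + 1e-9)
  })
})

test_that("monochorionic mixing fractions are recovered within 0.05", {
  ok <- 0; n <- 50
  withr::with_seed(92, for (i in 1:n) {
    m <- stats::runif(1, 1 - 0.83, 1 - 0.56)   # twin-2 share of the pool
    sim <- simulate_mixing_counts(m, 3, 3, seed = 7000 + i)
    est <- estimate_mixing(sim$informative, sim$counts,
                           c("cord1", "cord2"))
    if (all(abs(est$estimates$m - m) <= 0.05)) ok <- ok + 1
  })
  expect_gte(ok / n, 0.9)
})

test_that("co-twin cord samples of one shared pool agree within CIs", {
  withr::with_seed(93, for (i in 1:10) {
    m <- stats::runif(1, 0.2, 0.8)
    sim <- simulate_mixing_counts(m, 4, 4, seed = 800 + i)
    e <- estimate_mixing(sim$informative, sim$counts,
                         c("cord1", "cord2"))$estimates
    expect_true(e$ci_lo[1] <= e$ci_hi[2] && e$ci_lo[2] <= e$ci_hi[1])
  })
})

test_that("dichorionic twins show no cross-twin blood contribution", {
  # unmixed cords: Twin 1's cord carries only Twin-1-unique EEMs
  found <- 0
  for (s in 1:10) {
    fam <- simulate_family("D1", "MZ", "DCDA", mode = "para",
                           config = small_config(), seed = 900 + s)
    a <- analyse_family(fam, seed = s)
    if (is.null(a$mixing) || !identical(a$mixing$status, "ok")) next
    found <- found + 1
    est <- a$mixing$estimates
    # m = twin-2-lineage fraction: ~0 in Twin 1's cord, ~1 in Twin 2's;
    # allow the binomial read-noise SE of the estimate on top of the 0.02
    # biological bound
    k <- est$n_informative[1]
    se <- 2 * sqrt(0.25 / (700 * k))
    cross <- c(est$m[est$sample == "T1_cord_blood"],
               1 - est$m[est$sample == "T2_cord_blood"])
    expect_true(all(cross <= 0.02 + 3 * se))
    if (found >= 4) break
  }
  expect_gte(found, 2)
})
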