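test_that("anchor and counter-anchor clusters are found from constructed points", {
  pts <- data.frame(variant = paste0("m", 1:5),
                    v1 = c(0.48, 0.48, 0.48, 0.02, 0.02),
                    v2 = c(0.29, 0.29, 0.29, 0.21, 0.21))
  det <- detect_anchor_clusters(pts, model_config())
  expect_false(det$anchor_absent)
  expect_equal(unname(det$anchor$centroid), c(0.48, 0.29))
  expect_equal(unname(det$counter$centroid), c(0.02, 0.21))
  expect_true(det$symmetric)   # reflection of (0.48,0.29) is (0.02,0.21)
  # all cluster sums below 0.5: anchor absent, counter still returned
  low <- data.frame(variant = paste0("m", 1:4),
                    v1 = c(0.05, 0.05, 0.01, 0.01),
                    v2 = c(0.20, 0.20, 0.02, 0.02))
  det2 <- detect_anchor_clusters(low, model_config())
  expect_true(det2$anchor_absent)
  expect_equal(unname(det2$counter$centroid), c(0.05, 0.20))
  expect_error(detect_anchor_clusters(
    data.frame(variant = "x", v1 = NA_real_, v2 = NA_real_)), "no EEMs")
})

test_that("(a, b) estimation follows the cluster geometry", {
  cl <- function(v1, v2, size = 3)
    list(centroid = c(v1 = v1, v2 = v2), size = size, members = NULL)
  # para-identical geometry
  e1 <- estimate_ab(cl(0.5, 0), cl(0, 0.5))
  expect_equal(c(e1$a, e1$b), c(1, 0))
  expect_false(e1$swapped)
  # anchor only
  e2 <- estimate_ab(cl(0.5, 0.3), NULL)
  expect_equal(c(e2$a, e2$b), c(1.0, 0.6))
  # consistent anchor/counter pair: exact under both formulas
  e3 <- estimate_ab(cl(0.35, 0.30), cl(0.15, 0.20))
  expect_equal(c(e3$a, e3$b), c(0.7, 0.6))
  expect_equal(e3$source, "both")
  # counter only
  e4 <- estimate_ab(NULL, cl(0.15, 0.20))
  expect_equal(c(e4$a, e4$b), c(0.7, 0.6))
  expect_error(estimate_ab(NULL, NULL), "both clusters absent")
})

test_that("clonal categories tile (a, b) space with an epsilon band", {
  expect_equal(classify_category(1, 0), "para")
  expect_equal(classify_category(1, 0.6), "sub")
  expect_equal(classify_category(0.7, 0.6), "full")
  expect_equal(classify_category(0.95, 0.05, 0.1), "para")
  expect_equal(classify_category(0.85, 0.45), "discordant")
  expect_equal(classify_category(1, 1), "discordant")
  expect_error(classify_category(0.4, 0.6), "a >= b")
})

test_that("twin order is a labelling choice, not a result", {
  vp <- simulate_vaf_pairs(0.9, 0.4, seed = 71)
  f1 <- fit_anchor_model(vp)
  vp2 <- vp; vp2$v1 <- vp$v2; vp2$v2 <- vp$v1
  f2 <- fit_anchor_model(vp2)
  expect_equal(c(f1$a, f1$b), c(f2$a, f2$b), tolerance = 1e-12)
  expect_equal(f1$category, f2$category)
  expect_false(f1$swapped == f2$swapped)
})

test_that("(a, b) recovery from deep-targeted clusters", {
  ok <- 0; n <- 50
  withr::with_seed(81, for (i in 1:n) {
    repeat {
      ab <- sort(stats::runif(2)); a <- ab[2]; b <- ab[1]
      if (a + b >= 1) break
    }
    f <- fit_anchor_model(simulate_vaf_pairs(a, b, seed = i))
    if (abs(f$a - a) <= 0.05 && abs(f$b - b) <= 0.05) ok <- ok + 1
  })
  expect_gte(ok / n, 0.95)
})

test_that("genetic distance separates monoamniotic from diamniotic pairs", {
  cfg <- small_config()
  d_mono <- d_di <- c()
  for (s in 1:12) {
    fm <- simulate_family("A1", "MZ", "MCMA", mode = "full", config = cfg,
                          seed = 300 + s)
    fd <- simulate_family("A2", "MZ", "MCDA",
                          mode = sample(c("sub", "para"), 1), config = cfg,
                          seed = 400 + s)
    d_mono <- c(d_mono, genetic_distance(classify_variants(fm$table)))
    d_di <- c(d_di, genetic_distance(classify_variants(fd$table)))
  }
  expect_lt(mean(d_mono), mean(d_di))
  expect_lt(suppressWarnings(
    stats::wilcox.test(d_mono, d_di, alternative = "less"))$p.value, 0.05)
})

test_that("founder-separation divisions from unique clonal mutation counts", {
  expect_equal(divisions_between_founders(6, 1.2), 5L)
  expect_equal(divisions_between_founders(5, 1.2, "floor"), 4L)
  expect_equal(divisions_between_founders(0, 1.2), 0L)
  expect_error(divisions_between_founders(-1), ">= 0")
})

test_that("clonal-in-both EEMs are excluded from the two-lineage fit", {
  samples <- c("T1_buccal", "T2_buccal")
  d <- rbind(
    data.frame(family = "F", variant = "cb", sample = samples, depth = 700,
               alt = c(350, 340)),
    data.frame(family = "F", variant = "ok", sample = samples, depth = 700,
               alt = c(340, 10)))
  tab <- variant_table(d)
  calls <- data.frame(variant = c("cb", "ok"), class = "eem",
                      n_detected = 2, shared = TRUE)
  class(calls) <- c("variant_calls", "data.frame")
  vp <- eem_vaf_pairs(tab, calls, samples)
  expect_identical(vp$variant, "ok")
})
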