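test_that("zero-dropout matrices reconstruct the true clades exactly", {
  truth <- sc_truth_matrix(20, 5)
  sc0 <- sc_params(0, 0, 0, 40)
  ph <- reconstruct_sc_phylogeny(truth, sc = sc0)
  expect_equal(ph$status, "ok")
  top <- top_clade(ph$assignment)
  labels <- sc_truth_labels(20)
  acc <- mean(top == labels)
  flip <- mean(ifelse(top == "L1", "L2", "L1") == labels)
  expect_equal(max(acc, flip), 1)
  expect_match(ph$newick, "^\\(.*L1.*,.*L2.*\\);$|^\\(L[12]")
})

test_that("all-missing matrices fail with an explicit status", {
  m <- matrix(NA_integer_, 4, 3,
              dimnames = list(paste0("c", 1:4), paste0("m", 1:3)))
  ph <- reconstruct_sc_phylogeny(m, sc = sc_params())
  expect_match(ph$status, "missing")
  expect_error(reconstruct_sc_phylogeny(m[1, , drop = FALSE]), ">= 2 cells")
})

test_that("reconstruction is invariant to cell and variant input order", {
  truth <- sc_truth_matrix(25, 5)
  sc <- sc_params(0.23, 0.46, 0.01)
  obs <- withr::with_seed(101, noisy_sc_matrix(truth, sc))
  mk <- list(paste0("m", 1:5), paste0("m", 6:10))
  ph1 <- reconstruct_sc_phylogeny(obs, markers = mk, sc = sc)
  perm <- withr::with_seed(5, sample(nrow(obs)))
  vperm <- withr::with_seed(6, sample(ncol(obs)))
  ph2 <- reconstruct_sc_phylogeny(obs[perm, vperm], markers = mk, sc = sc)
  expect_identical(ph1$assignment[rownames(obs)[perm]], ph2$assignment)
})

test_that("cell assignment stays accurate under the estimated dropout rates", {
  sc <- sc_params(0.23, 0.46, 0.01)
  accs <- withr::with_seed(103, vapply(1:50, function(i) {
    truth <- sc_truth_matrix(40, 5)
    obs <- noisy_sc_matrix(truth, sc)
    ph <- reconstruct_sc_phylogeny(
      obs, markers = list(paste0("m", 1:5), paste0("m", 6:10)), sc = sc)
    mean(top_clade(ph$assignment) == sc_truth_labels(40))
  }, double(1)))
  expect_gte(mean(accs), 0.9)
})

test_that("assignment accuracy degrades monotonically with dropout", {
  # coupled noise: the same uniform draws thresholded at increasing rates
  lam_grid <- c(0.1, 0.46, 0.7)
  accs <- withr::with_seed(104, {
    out <- matrix(NA_real_, 20, length(lam_grid))
    for (r in 1:20) {
      truth <- sc_truth_matrix(40, 5)
      u_miss <- matrix(stats::runif(length(truth)), nrow(truth))
      u_ado <- matrix(stats::runif(length(truth)), nrow(truth))
      u_fp <- matrix(stats::runif(length(truth)), nrow(truth))
      for (j in seq_along(lam_grid)) {
        sc <- sc_params(0.23, lam_grid[j], 0.01)
        obs <- ifelse(truth == 1L, ifelse(u_ado < sc$ado_rate, 0L, 1L),
                      ifelse(u_fp < sc$fp_rate, 1L, 0L))
        obs[u_miss < sc$locus_dropout] <- NA_integer_
        dimnames(obs) <- dimnames(truth)
        ph <- reconstruct_sc_phylogeny(
          obs, markers = list(paste0("m", 1:5), paste0("m", 6:10)),
          sc = sc)
        out[r, j] <- mean(top_clade(ph$assignment) == sc_truth_labels(40))
      }
    }
    out
  })
  m <- colMeans(accs)
  expect_true(all(diff(m) <= 0.02))   # non-increasing up to noise slack
})

test_that("a marker co-occurring with the opposite clade is reassigned downstream", {
  # m6 is a true L2 marker; m7 is claimed for L2 by the bulk fit but in
  # truth sits downstream of L1 (co-occurs with L1 markers)
  n <- 30
  truth <- rbind(
    cbind(sc_truth_matrix(n, 5)[1:n, ], m11 = rep(1L, n)),
    cbind(sc_truth_matrix(n, 5)[(n + 1):(2 * n), ], m11 = rep(0L, n)))
  colnames(truth) <- c(paste0("m", 1:10), "m7x")
  sc <- sc_params(0.1, 0.2, 0.01)
  obs <- withr::with_seed(105, noisy_sc_matrix(truth, sc))
  ph <- reconstruct_sc_phylogeny(
    obs, markers = list(paste0("m", 1:5), c(paste0("m", 6:10), "m7x")),
    sc = sc)
  expect_false("m7x" %in% ph$clades$L2)
  acc <- mean(top_clade(ph$assignment) == sc_truth_labels(n))
  expect_gte(acc, 0.9)
})

test_that("lineage contributions are clade fractions with binomial CIs", {
  assignment <- stats::setNames(
    rep(c("L1", "L2"), c(36, 41)), paste0("c", 1:77))
  ph <- structure(list(status = "ok", assignment = assignment),
                  class = "sc_phylogeny")
  cell_twin <- rep(c("T1", "T2"), c(36, 41))
  lc <- lineage_contribution(ph, cell_twin)
  expect_equal(lc$fraction[lc$individual == "T1" & lc$clade == "L1"], 1)
  expect_equal(lc$fraction[lc$individual == "T2" & lc$clade == "L2"], 1)
  expect_equal(lc$n[lc$individual == "T2" & lc$clade == "L2"], 41)
  mixed <- lineage_contribution(ph, rep("T1", 77))
  f <- mixed$fraction[mixed$clade == "L1"]
  expect_equal(f, 36 / 77)
  expect_true(mixed$ci_lo[mixed$clade == "L1"] < f &&
                f < mixed$ci_hi[mixed$clade == "L1"])
})

test_that("single cells confirm bulk lineage contributions in a full pair", {
  cfg <- small_config()
  fam <- simulate_family("S1", "MZ", "MCMA", mode = "full", config = cfg,
                         seed = 120)
  tr <- fam$trees[[1]]
  sc <- sc_params(0.23, 0.46, 0.01, 60)
  eems <- which(tr$catalog$origin_class == "eem" &
                  tr$catalog$origin_node %in% 2:3)
  pb1 <- sample_tissue(tr, fam$partition, "twin1", "pbmc", 128,
                       individual = "T1", seed = 121)
  pb2 <- sample_tissue(tr, fam$partition, "twin2", "pbmc", 128,
                       individual = "T2", seed = 122)
  m1 <- simulate_single_cells(tr, pb1, sc, variants = eems, seed = 123)
  m2 <- simulate_single_cells(tr, pb2, sc, variants = eems, seed = 124)
  obs <- rbind(m1, m2)
  l1 <- paste0("m", tr$catalog$mut_id[eems[
    tr$catalog$origin_node[eems] == fam$partition$L1_node]])
  l2 <- paste0("m", tr$catalog$mut_id[eems[
    tr$catalog$origin_node[eems] == fam$partition$L2_node]])
  if (length(l1) >= 2 && length(l2) >= 2) {
    ph <- reconstruct_sc_phylogeny(obs, markers = list(l1, l2), sc = sc)
    lc <- lineage_contribution(ph, rep(c("T1", "T2"), each = 60))
    got <- lc$fraction[lc$clade == "L1"]
    want <- c(fam$truth$true_a, fam$truth$true_b)
    expect_true(all(abs(got - want) < 0.2))
  } else succeed("too few gen-1 markers in this draw")
})
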