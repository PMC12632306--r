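# shared fixtures built in code

# small, fast study configuration for cohort-level tests
small_config <- function(params = sim_params(n_generations = 8), ...) {
  cohort_config(n_mcma = 1, n_mcda = 1, n_dcda = 1, n_triplet = 0,
                n_dz = 1, params = params, ...)
}

# two-clade single-cell truth matrix: n cells per clade, k markers per clade
sc_truth_matrix <- function(n_per = 40, k = 5) {
  truth <- rbind(
    matrix(rep(c(rep(1L, k), rep(0L, k)), each = n_per), nrow = n_per),
    matrix(rep(c(rep(0L, k), rep(1L, k)), each = n_per), nrow = n_per))
  dimnames(truth) <- list(paste0("c", seq_len(2 * n_per)),
                          paste0("m", seq_len(2 * k)))
  truth
}

sc_truth_labels <- function(n_per = 40) rep(c("L1", "L2"), each = n_per)

noisy_sc_matrix <- function(truth, sc) {
  obs <- twinEEM:::apply_sc_noise(truth, sc)
  dimnames(obs) <- dimnames(truth)
  obs
}

top_clade <- function(assignment) sub("^(L[12]).*", "\\1", assignment)

# random small variant table for round-trip property tests
random_variant_table <- function(seed, n_var = 8, n_samp = 3) {
  withr::with_seed(seed, {
    vids <- paste0("v", seq_len(n_var))
    samples <- paste0("T", seq_len(n_samp), "_buccal")
    d <- expand.grid(variant = vids, sample = samples,
                     stringsAsFactors = FALSE)
    d$family <- "FAM1"
    d$depth <- rpois(nrow(d), 60)
    d$alt <- rbinom(nrow(d), d$depth, runif(nrow(d)))
    variants <- data.frame(
      variant = vids,
      chrom = paste0("chr", sample(1:22, n_var, TRUE)),
      pos = sample(1e6, n_var), ref = sample(c("A", "C", "G", "T"), n_var, TRUE),
      alt = sample(c("A", "C", "G", "T"), n_var, TRUE),
      mother = sample(c(TRUE, FALSE), n_var, TRUE),
      father = sample(c(TRUE, FALSE), n_var, TRUE),
      stringsAsFactors = FALSE)
    variant_table(d[, c("family", "variant", "sample", "depth", "alt")],
                  variants, samples)
  })
}
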