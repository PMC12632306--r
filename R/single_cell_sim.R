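#' Single-cell amplification error parameters
#'
#' Error model of MDA-amplified single-genome sequencing: a site drops out
#' entirely (locus dropout) with probability `locus_dropout`; otherwise a
#' heterozygous variant allele is lost (allelic dropout) with probability
#' `ado_rate`, and a reference site is miscalled alt with probability
#' `fp_rate`.
#'
#' @param ado_rate allelic dropout probability (default 0.23).
#' @param locus_dropout locus dropout probability (default 0.46).
#' @param fp_rate false-positive alt-call probability (default 0.01).
#' @param n_cells number of cells to simulate.
#' @return object of class `sc_params`.
#' @export
sc_params <- function(ado_rate = 0.23, locus_dropout = 0.46, fp_rate = 0.01,
                      n_cells = 80) {
  for (r in c(ado_rate, locus_dropout, fp_rate))
    if (r < 0 || r >= 1) stop_arg("single-cell rates must be in [0, 1)")
  structure(list(ado_rate = ado_rate, locus_dropout = locus_dropout,
                 fp_rate = fp_rate, n_cells = as.integer(n_cells)),
            class = "sc_params")
}

#' Simulate a single-cell genotype matrix from a tissue sample
#'
#' Cells are drawn (with replacement) from the tissue's progenitor cells and
#' genotyped at the given catalog variants under the dropout model: each
#' entry is missing with probability `locus_dropout`; otherwise a true alt
#' is observed as alt with probability `1 - ado_rate` (ref otherwise) and a
#' true ref is observed as alt with probability `fp_rate`.
#'
#' @param tree the `lineage_tree` the sample came from.
#' @param sample a `tissue_sample` with progenitor cells.
#' @param sc an [sc_params()] object.
#' @param variants integer vector of catalog rows to genotype.
#' @param seed optional integer seed.
#' @return an `sc_genotype_matrix`: integer matrix cells x variants with
#'   entries 0 (ref), 1 (alt), NA (missing); attributes `cell_twin`
#'   (individual id per cell), `true_genotype` (same shape, 0/1) and
#'   `sc_params`.
#' @export
simulate_single_cells <- function(tree, sample, sc = sc_params(),
                                  variants = NULL, seed = NULL) {
  if (is.null(sample$progenitors))
    stop_arg("sample has no underlying cell list (pooled/mixed sample?)")
  with_seed(seed, {
    variants <- variants %||% seq_len(nrow(tree$catalog))
    cells <- sample(sample$progenitors, sc$n_cells, replace = TRUE)
    rng <- subtree_leaf_range(tree$catalog$origin_node[variants],
                              tree$n_generations)
    truth <- vapply(seq_along(variants), function(j) {
      as.integer(cells >= rng[j, "lo"] & cells <= rng[j, "hi"])
    }, integer(sc$n_cells))
    truth <- matrix(truth, nrow = sc$n_cells)
    obs <- apply_sc_noise(truth, sc)
    dimnames(obs) <- list(paste0(sample$individual, "_cell",
                                 seq_len(sc$n_cells)),
                          paste0("m", tree$catalog$mut_id[variants]))
    structure(obs,
              cell_twin = rep(sample$individual, sc$n_cells),
              true_genotype = truth, sc_params = sc,
              class = c("sc_genotype_matrix", "matrix", "array"))
  })
}

# apply the dropout/error model to a 0/1 truth matrix
apply_sc_noise <- function(truth, sc) {
  n <- length(truth)
  miss <- stats::runif(n) < sc$locus_dropout
  ado <- stats::runif(n) < sc$ado_rate
  fp <- stats::runif(n) < sc$fp_rate
  obs <- ifelse(truth == 1L, ifelse(ado, 0L, 1L), ifelse(fp, 1L, 0L))
  obs[miss] <- NA_integer_
  matrix(obs, nrow = nrow(truth))
}
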