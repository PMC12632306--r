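#' Found a tissue by bottleneck sampling of progenitors
#'
#' Draws `n_progenitors` terminal cells from a twin's founder lineage and
#' records, for every mutation in the catalog, the carrier cell fraction in
#' the tissue. De novo variants are heterozygous in every cell (fraction 1,
#' true VAF 0.5); EEM fractions are `carriers / n_progenitors` so the true
#' VAF lies in `[0, 0.5]`.
#'
#' @param tree a `lineage_tree`.
#' @param partition a `twin_partition`, or a plain list of founder-cell
#'   vectors (e.g. from [simulate_triplet()]).
#' @param twin twin name in `partition$founders` (e.g. `"twin1"`).
#' @param tissue tissue label; one of buccal, cord_blood, umbilical_cord,
#'   placenta_patch, pbmc.
#' @param n_progenitors bottleneck size (number of progenitor cells).
#' @param individual individual id used in the sample name.
#' @param seed optional integer seed.
#' @return an object of class `tissue_sample`: sample/individual/tissue ids,
#'   `progenitors` (leaf node ids), `cell_fraction` and `true_vaf` vectors
#'   aligned to the catalog rows.
#' @export
sample_tissue <- function(tree, partition, twin, tissue, n_progenitors = 32,
                          individual = twin, seed = NULL) {
  tissues <- c("buccal", "cord_blood", "umbilical_cord", "placenta_patch",
               "pbmc")
  if (!tissue %in% tissues)
    stop_arg("unknown tissue '%s'", tissue)
  founders <- partition$founders[[twin]]
  if (is.null(founders)) stop_arg("unknown twin '%s'", twin)
  if (n_progenitors < 1) stop_arg("n_progenitors must be >= 1")
  with_seed(seed, {
    leaves <- if (inherits(partition, "twin_partition"))
      twin_leaves(tree, partition, twin)
    else {
      rng <- subtree_leaf_range(founders, tree$n_generations)
      unlist(lapply(seq_along(founders),
                    function(i) seq.int(rng[i, "lo"], rng[i, "hi"])),
             use.names = FALSE)
    }
    prog <- if (length(leaves) >= n_progenitors)
      sample(leaves, n_progenitors) else sample(leaves, n_progenitors, TRUE)
    cf <- carrier_fraction(tree, prog)
    cf[tree$catalog$origin_class == "denovo"] <- 1
    structure(list(sample_id = paste(individual, tissue, sep = "_"),
                   individual = individual, tissue = tissue,
                   progenitors = prog, cell_fraction = cf,
                   true_vaf = cf / 2),
              class = "tissue_sample")
  })
}

#' Sequence a tissue sample
#'
#' Binomial read sampling: depth per site is Poisson with the regime's mean
#' depth, and alt reads are Binomial(depth, p) with
#' `p = VAF (1 - e) + (1 - VAF) e / 3` for per-base error rate `e`.
#'
#' @param sample a `tissue_sample` (or anything with a `true_vaf` vector).
#' @param params a [sim_params()].
#' @param regime `"wgs"` (mean `wgs_depth`) or `"targeted"`
#'   (mean `targeted_depth`).
#' @param variants optional integer vector of catalog rows to sequence
#'   (default: all).
#' @param seed optional integer seed.
#' @return data.frame (mut_id, depth, alt, vaf); `vaf` is `NA` when depth
#'   is 0.
#' @export
sequence_sample <- function(sample, params, regime = c("wgs", "targeted"),
                            variants = NULL, seed = NULL) {
  regime <- match.arg(regime)
  with_seed(seed, {
    v <- sample$true_vaf
    idx <- variants %||% seq_along(v)
    v <- v[idx]
    mean_depth <- switch(regime, wgs = params$wgs_depth,
                         targeted = params$targeted_depth)
    e <- params$seq_error
    depth <- stats::rpois(length(v), mean_depth)
    p <- v * (1 - e) + (1 - v) * e / 3
    alt <- stats::rbinom(length(v), depth, p)
    data.frame(mut_id = idx, depth = depth, alt = alt,
               vaf = ifelse(depth > 0, alt / depth, NA_real_))
  })
}

#' Found and sequence a tissue in one step
#'
#' @inheritParams sample_tissue
#' @inheritParams sequence_sample
#' @return list with the `tissue_sample` and its read-count data.frame.
#' @export
sample_and_sequence <- function(tree, partition, twin, tissue,
                                n_progenitors = 32,
                                regime = c("wgs", "targeted"),
                                params = sim_params(), individual = twin,
                                seed = NULL) {
  regime <- match.arg(regime)
  with_seed(seed, {
    ts <- sample_tissue(tree, partition, twin, tissue, n_progenitors,
                        individual)
    list(sample = ts, counts = sequence_sample(ts, params, regime))
  })
}

#' Mix two co-twins' cord blood through a shared placental circulation
#'
#' Monochorionic twins share one hematopoietic pool: both cord-blood samples
#' become the same linear mixture with fraction `f` of cells from Twin 1's
#' hematopoietic lineage. Dichorionic twins have separate circulations and
#' the samples are returned unchanged.
#'
#' @param blood1,blood2 `tissue_sample` objects for the two twins' blood.
#' @param f fraction of the common pool derived from Twin 1's lineage,
#'   in `[0, 1]`.
#' @param chorionicity `"monochorionic"` or `"dichorionic"`.
#' @return list of the two (possibly mixed) `tissue_sample` objects.
#' @export
mix_cord_blood <- function(blood1, blood2, f,
                           chorionicity = c("monochorionic", "dichorionic")) {
  chorionicity <- match.arg(chorionicity)
  if (f < 0 || f > 1) stop_arg("f must be in [0, 1]")
  if (chorionicity == "dichorionic") return(list(blood1, blood2))
  cf <- f * blood1$cell_fraction + (1 - f) * blood2$cell_fraction
  mk <- function(b) {
    b$cell_fraction <- cf
    b$true_vaf <- cf / 2
    b$progenitors <- NULL  # pooled sample no longer maps to single leaves
    b$mixed_f <- f
    b
  }
  list(mk(blood1), mk(blood2))
}

#' Model-expected anchor and counter-anchor VAFs
#'
#' Under the two-lineage model with L1 contributing fractions `a` and `b`
#' to Twin 1 and Twin 2, anchor EEMs (carried by L1) sit at VAFs
#' `(a/2, b/2)` and counter-anchor EEMs (carried by L2) at
#' `((1-a)/2, (1-b)/2)`; the two cluster positions are always point-symmetric
#' through (0.25, 0.25).
#'
#' @param a,b contributions of L1 to Twin 1 and Twin 2, in `[0, 1]`.
#' @return list with `anchor`, `counter` (length-2 VAF vectors) and
#'   `midpoint`.
#' @export
model_expected_vafs <- function(a, b) {
  stopifnot(a >= 0, a <= 1, b >= 0, b <= 1)
  anchor <- c(a / 2, b / 2)
  counter <- c((1 - a) / 2, (1 - b) / 2)
  list(anchor = anchor, counter = counter,
       midpoint = (anchor + counter) / 2)
}
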