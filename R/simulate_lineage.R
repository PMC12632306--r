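#' Simulation parameters for the embryo forward model
#'
#' Bundles the knobs of the forward simulation: the post-zygotic mutation
#' rate, tree depth, the pre-zygotic de novo variant load, sequencing depths
#' and the variant-detection rule.
#'
#' @param mutation_rate expected new early embryonic mutations (EEMs) per
#'   daughter cell per division. Default 1.2, the clock-like rate of early
#'   embryogenesis.
#' @param n_generations depth of the cell-division tree (zygote = generation
#'   0). Default 12, i.e. 4096 terminal cells, deep enough that tissue
#'   bottlenecks resolve anchor VAFs at whole-genome depth.
#' @param denovo_count number of heterozygous pre-zygotic de novo variants
#'   carried by the zygote. Default 68 (cohort median 67.5).
#' @param wgs_depth mean whole-genome read depth (default 60).
#' @param targeted_depth mean deep-targeted read depth (default 700).
#' @param seq_error per-base sequencing error rate (default 0.001); an error
#'   is spread equally over the 3 non-template bases.
#' @param detection_min_alt minimum alt reads to call a variant present
#'   (default 3).
#' @param detection_min_vaf minimum VAF to call a variant present
#'   (default 0.03).
#' @param genome_size virtual genome length in bp for mutation placement
#'   (default 3.0e9, 24 chromosomes of 125 Mb).
#' @param seed optional integer seed.
#' @return an object of class `sim_params` (a validated list).
#' @export
sim_params <- function(mutation_rate = 1.2, n_generations = 12,
                       denovo_count = 68, wgs_depth = 60,
                       targeted_depth = 700, seq_error = 0.001,
                       detection_min_alt = 3, detection_min_vaf = 0.03,
                       genome_size = 3.0e9, seed = NULL) {
  if (mutation_rate < 0) stop_arg("mutation_rate must be >= 0")
  if (n_generations < 1) stop_arg("n_generations must be >= 1")
  if (wgs_depth <= 0 || targeted_depth <= 0) stop_arg("depths must be > 0")
  if (seq_error < 0 || seq_error >= 0.5) stop_arg("seq_error must be in [0, 0.5)")
  structure(list(mutation_rate = mutation_rate,
                 n_generations = as.integer(n_generations),
                 denovo_count = as.integer(denovo_count),
                 wgs_depth = wgs_depth, targeted_depth = targeted_depth,
                 seq_error = seq_error,
                 detection_min_alt = as.integer(detection_min_alt),
                 detection_min_vaf = detection_min_vaf,
                 genome_size = genome_size, seed = seed),
            class = "sim_params")
}

# -- complete binary tree helpers (heap indexing: root = 1, children 2k, 2k+1)

node_generation <- function(id) as.integer(floor(log2(id)))

# leaf-index range [lo, hi] of the subtree below `node` in a tree of depth G
subtree_leaf_range <- function(node, G) {
  g <- node_generation(node)
  width <- 2^(G - g)
  lo <- node * width
  cbind(lo = lo, hi = lo + width - 1)
}

# all nodes of generation g
generation_nodes <- function(g) seq.int(2^g, 2^(g + 1) - 1)

# node ids on the path from `node` up to (and including) the root
path_to_root <- function(node) {
  out <- integer(0)
  while (node >= 1) {
    out <- c(out, node)
    node <- node %/% 2
  }
  out
}

#' Forward-simulate an embryonic cell-division lineage tree
#'
#' Grows a complete binary tree from the zygote to `n_generations`. Every
#' non-root cell acquires a Poisson(`mutation_rate`) number of new EEMs which
#' are inherited by all of its descendants; the zygote carries
#' `denovo_count` pre-zygotic de novo variants. Mutation positions are drawn
#' uniformly without replacement from a virtual genome so independent zygotes
#' essentially never collide.
#'
#' @param params a [sim_params()] object.
#' @param seed optional integer seed (overrides `params$seed`).
#' @return a list with class `lineage_tree`:
#'   \describe{
#'     \item{n_generations}{tree depth.}
#'     \item{mut_node}{integer vector, origin node of each mutation.}
#'     \item{catalog}{data.frame (mut_id, chrom, pos, ref, alt, origin_node,
#'       origin_class) with origin_class in \{denovo, eem\}.}
#'   }
#' @examples
#' tr <- simulate_lineage(sim_params(n_generations = 4, seed = 1))
#' table(tr$catalog$origin_class)
#' @export
simulate_lineage <- function(params = sim_params(), seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  seed <- seed %||% params$seed
  with_seed(seed, {
    G <- params$n_generations
    n_nodes <- 2^(G + 1) - 1
    nonroot <- 2:n_nodes
    eem_counts <- stats::rpois(length(nonroot), params$mutation_rate)
    eem_nodes <- rep(nonroot, eem_counts)
    origin_node <- c(rep(1L, params$denovo_count), eem_nodes)
    n_mut <- length(origin_node)
    pos_global <- sample(params$genome_size, n_mut, replace = FALSE)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_mut, replace = TRUE)
    alt_off <- sample(3L, n_mut, replace = TRUE)
    alt <- bases[(match(ref, bases) - 1L + alt_off) %% 4L + 1L]
    chrom_len <- 125e6
    catalog <- data.frame(
      mut_id = seq_len(n_mut),
      chrom = paste0("chr", 1 + (pos_global - 1) %/% chrom_len),
      pos = as.integer((pos_global - 1) %% chrom_len + 1),
      ref = ref, alt = alt,
      origin_node = origin_node,
      origin_class = ifelse(origin_node == 1L, "denovo", "eem"),
      stringsAsFactors = FALSE
    )
    structure(list(n_generations = G, mut_node = origin_node,
                   catalog = catalog),
              class = "lineage_tree")
  })
}

#' Mutation carrier fraction among a set of terminal cells
#'
#' For each mutation in the catalog, the fraction of the given terminal
#' (leaf) cells descending from the mutation's origin node, i.e. the
#' cell fraction carrying the mutation.
#'
#' @param tree a `lineage_tree`.
#' @param leaves integer vector of leaf node ids (generation `n_generations`).
#' @return numeric vector over catalog rows, in `[0, 1]`.
#' @keywords internal
carrier_fraction <- function(tree, leaves) {
  G <- tree$n_generations
  rng <- subtree_leaf_range(tree$catalog$origin_node, G)
  ls <- sort(as.numeric(leaves))
  # carriers = number of leaves with id in [lo, hi]
  n_le <- findInterval(rng[, "hi"], ls)
  n_lt <- findInterval(rng[, "lo"] - 0.5, ls)
  (n_le - n_lt) / length(leaves)
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("lineage_tree: depth %d (%d terminal cells), %d de novo + %d EEMs\n",
              x$n_generations, 2^x$n_generations,
              sum(x$catalog$origin_class == "denovo"),
              sum(x$catalog$origin_class == "eem")))
  invisible(x)
}
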