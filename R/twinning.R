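#' Split an embryo into twins
#'
#' Partitions the cells of one generation of the lineage tree into the two
#' co-twins' founder pools, following one of the three clonal architectures:
#' \describe{
#'   \item{para}{complete segregation of the two daughter lineages of a
#'     chosen ancestral cell: the twins descend from two independent early
#'     lineages, (a, b) = (1, 0).}
#'   \item{sub}{Twin 1 buds from a single cell at `split_generation`; Twin 2
#'     is founded by all remaining contemporaneous cells, so Twin 1 is a
#'     clonal subset of the embryo (a = 1, 0 < b < 1).}
#'   \item{full}{cells at `split_generation` are randomly partitioned with
#'     Twin-1 share `allocation`; both twins are mixtures of both early
#'     lineages (a close to b).}
#' }
#' L1 is the earliest lineage (a generation-1 cell, or for full mode the
#' generation-1 lineage with the larger combined contribution) and Twin 1 is
#' ordered so that `true_a >= true_b`.
#'
#' @param tree a `lineage_tree` from [simulate_lineage()].
#' @param mode one of `"para"`, `"sub"`, `"full"`.
#' @param split_generation generation at which twinning occurs; for
#'   `"para"` the chosen ancestor sits at `split_generation - 1` (default 1:
#'   the two daughters of the zygote).
#' @param allocation Twin-1 share of cells for `mode = "full"`, in (0, 1).
#' @param seed optional integer seed.
#' @return an object of class `twin_partition`: founder cells per twin
#'   (node ids at `split_generation`), `mode`, `split_generation`,
#'   `true_a`, `true_b`, `L1_node`, `L2_node`.
#' @export
apply_twinning <- function(tree, mode = c("full", "sub", "para"),
                           split_generation = NULL, allocation = 0.5,
                           seed = NULL) {
  stopifnot(inherits(tree, "lineage_tree"))
  mode <- match.arg(mode)
  G <- tree$n_generations
  g <- split_generation %||% switch(mode, para = 1L, sub = 6L, full = 7L)
  g <- as.integer(g)
  if (g < 1 || g >= G) stop_arg("split_generation must be in [1, n_generations)")
  with_seed(seed, {
    cells <- generation_nodes(g)
    if (mode == "para") {
      anc <- if (g == 1L) 1L else sample(generation_nodes(g - 1L), 1L)
      d1 <- 2L * anc
      d2 <- d1 + 1L
      founders <- list(twin1 = d1, twin2 = d2)
      res <- list(founders = founders, true_a = 1, true_b = 0,
                  L1_node = d1, L2_node = d2)
    } else if (mode == "sub") {
      f1 <- sample(cells, 1L)
      founders <- list(twin1 = f1, twin2 = setdiff(cells, f1))
      L1 <- path_to_root(f1)
      L1 <- L1[length(L1) - 1L]  # generation-1 ancestor of the budding cell
      L2 <- if (L1 == 2L) 3L else 2L
      under_L1 <- subtree_leaf_range(L1, g)  # gen-g cells below L1
      n_L1 <- under_L1[, "hi"] - under_L1[, "lo"] + 1
      res <- list(founders = founders, true_a = 1,
                  true_b = unname((n_L1 - 1) / (length(cells) - 1)),
                  L1_node = L1, L2_node = L2)
    } else {
      if (allocation <= 0 || allocation >= 1)
        stop_arg("allocation must be in (0, 1) for mode = 'full'")
      n1 <- max(1L, min(length(cells) - 1L,
                        round(allocation * length(cells))))
      t1 <- sort(sample(cells, n1))
      t2 <- setdiff(cells, t1)
      r2 <- subtree_leaf_range(2L, g)  # gen-g cells below node 2
      in2 <- function(v) mean(v >= r2[, "lo"] & v <= r2[, "hi"])
      a2 <- in2(t1); b2 <- in2(t2)
      if (a2 + b2 >= 1) {
        L1 <- 2L; a <- a2; b <- b2
      } else {
        L1 <- 3L; a <- 1 - a2; b <- 1 - b2
      }
      founders <- list(twin1 = t1, twin2 = t2)
      if (b > a) {  # Twin-1 convention: a >= b
        founders <- list(twin1 = t2, twin2 = t1)
        tmp <- a; a <- b; b <- tmp
      }
      res <- list(founders = founders, true_a = a, true_b = b,
                  L1_node = L1, L2_node = if (L1 == 2L) 3L else 2L)
    }
    structure(c(res, list(mode = mode, split_generation = g)),
              class = "twin_partition")
  })
}

# terminal cells (leaves) descending from a twin's founder cells
twin_leaves <- function(tree, partition, twin) {
  founders <- partition$founders[[twin]]
  G <- tree$n_generations
  rng <- subtree_leaf_range(founders, G)
  unlist(lapply(seq_along(founders),
                function(i) seq.int(rng[i, "lo"], rng[i, "hi"])),
         use.names = FALSE)
}

#' Split an embryo into a monozygotic triplet
#'
#' Two consecutive budding (sub-mode) events: at `g1` one cell buds off to
#' found the later (Triplet 1 + Triplet 2) precursor while the remaining
#' cells found Triplet 3; at `g2` the precursor's subtree splits again, one
#' cell founding Triplet 1 and the rest Triplet 2. The true topology is
#' therefore ((T1,T2),T3) with the T1/T2 ancestor the later MRCA.
#'
#' @param tree a `lineage_tree`.
#' @param g1,g2 generations of the two budding events (`g1 < g2`).
#' @param seed optional integer seed.
#' @return list of three founder-cell vectors (`T1`, `T2`, `T3`) plus the
#'   true Newick topology.
#' @export
simulate_triplet <- function(tree, g1 = 4L, g2 = 7L, seed = NULL) {
  stopifnot(inherits(tree, "lineage_tree"), g1 < g2,
            g2 < tree$n_generations)
  with_seed(seed, {
    cells1 <- generation_nodes(g1)
    pre <- sample(cells1, 1L)                    # T1+T2 precursor
    t3 <- setdiff(cells1, pre)
    rng <- subtree_leaf_range(pre, g2)           # precursor cells at g2
    cells2 <- seq.int(rng[, "lo"], rng[, "hi"])
    f1 <- sample(cells2, 1L)
    list(founders = list(T1 = f1, T2 = setdiff(cells2, f1), T3 = t3),
         precursor = pre, g1 = as.integer(g1), g2 = as.integer(g2),
         true_topology = "((T1,T2),T3);")
  })
}
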