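#' Anchor-model configuration
#'
#' @param link_radius single-linkage merge radius in 2-D VAF space
#'   (default 0.05, roughly 2--3 binomial SDs at deep-targeted depth).
#' @param symmetry_tol maximal distance between the counter-anchor centroid
#'   and the point reflection of the anchor centroid through (0.25, 0.25)
#'   (default 0.10).
#' @param anchor_sum_min minimal summed centroid VAF across both twins for
#'   an anchor cluster (0.5: L1 explains at least half of both somas
#'   combined).
#' @param epsilon tolerance for the category boundaries `a = 1`, `b = 0`,
#'   `a = b` (default 0.10).
#' @param min_cluster_size minimal EEM count per cluster (default 2).
#' @param founder_rate mutations per cell per division used to convert
#'   mutation counts to divisions (default 1.2).
#' @return object of class `model_config`.
#' @export
model_config <- function(link_radius = 0.05, symmetry_tol = 0.10,
                         anchor_sum_min = 0.5, epsilon = 0.10,
                         min_cluster_size = 2, founder_rate = 1.2) {
  stopifnot(link_radius > 0, link_radius < 1, symmetry_tol > 0,
            epsilon > 0, epsilon < 1, min_cluster_size >= 1,
            founder_rate > 0)
  structure(list(link_radius = link_radius, symmetry_tol = symmetry_tol,
                 anchor_sum_min = anchor_sum_min, epsilon = epsilon,
                 min_cluster_size = as.integer(min_cluster_size),
                 founder_rate = founder_rate),
            class = "model_config")
}

# diameter-bounded (complete-linkage) clusters of EEMs in twin-vs-twin VAF
# space; single linkage chains along the subclonal VAF continuum and
# absorbs the anchor, so clusters are cut by maximal diameter instead
.vaf_clusters <- function(pairs, link_radius) {
  xy <- cbind(pairs$v1, pairs$v2)
  cl <- if (nrow(xy) == 1) 1L else
    stats::cutree(stats::hclust(stats::dist(xy), method = "complete"),
                  h = 2 * link_radius)
  lapply(split(seq_len(nrow(xy)), cl), function(idx) {
    list(members = as.character(pairs$variant[idx]), idx = idx,
         size = length(idx),
         centroid = c(v1 = mean(pairs$v1[idx]), v2 = mean(pairs$v2[idx])),
         var1 = if (length(idx) > 1) stats::var(pairs$v1[idx]) else 0)
  })
}

#' Detect anchor and counter-anchor EEM clusters
#'
#' Clusters EEM VAF pairs (Twin 1 VAF, Twin 2 VAF) by single linkage and
#' identifies: the anchor cluster — the cluster of size at least
#' `min_cluster_size` with maximal summed centroid VAF among those with sum
#' at least `anchor_sum_min` (L1's mutations); and the counter-anchor — the
#' cluster whose centroid is nearest the point reflection of the anchor
#' centroid through (0.25, 0.25), within `symmetry_tol` (L2's mutations).
#' When no cluster reaches the anchor sum rule (sparse L1 mutation load),
#' the counter-anchor is identified alone as the largest-summed-VAF cluster
#' below the anchor threshold — the complementary-lineage cluster, whose
#' sum is `1 -` the (unobserved) anchor sum and therefore dominates any
#' deeper sublineage cluster.
#'
#' @param pairs data.frame with columns `variant`, `v1`, `v2` (EEM VAFs in
#'   Twin 1 and Twin 2).
#' @param config a [model_config()].
#' @return list with `anchor` (cluster or NULL), `counter` (cluster or
#'   NULL), `clusters` (all clusters) and `anchor_absent` flag. Each
#'   cluster is a list (members, size, centroid).
#' @examples
#' pts <- data.frame(variant = paste0("m", 1:5),
#'                   v1 = c(.48, .48, .48, .02, .02),
#'                   v2 = c(.29, .29, .29, .21, .21))
#' detect_anchor_clusters(pts, model_config())$anchor$centroid
#' @export
detect_anchor_clusters <- function(pairs, config = model_config()) {
  pairs <- pairs[stats::complete.cases(pairs[, c("v1", "v2")]), ]
  if (!nrow(pairs)) stop_arg("no EEMs with VAFs in both twins")
  cls <- .vaf_clusters(pairs, config$link_radius)
  sums <- vapply(cls, function(c) sum(c$centroid), double(1))
  sizes <- vapply(cls, function(c) c$size, double(1))
  big <- sizes >= config$min_cluster_size
  cand <- which(big & sums >= config$anchor_sum_min)
  anchor <- counter <- NULL
  symmetric <- FALSE
  if (length(cand)) {
    # max centroid sum; ties -> larger cluster, then lower twin-1 variance
    o <- cand[order(-sums[cand], -sizes[cand],
                    vapply(cls[cand], function(c) c$var1, double(1)))]
    anchor <- cls[[o[1]]]
    refl <- c(0.5, 0.5) - anchor$centroid
    rest <- setdiff(seq_along(cls), o[1])
    if (length(rest)) {
      dd <- vapply(cls[rest], function(c)
        sqrt(sum((c$centroid - refl)^2)), double(1))
      ok <- dd <= config$symmetry_tol
      if (any(ok)) {
        ok_big <- ok & sizes[rest] >= config$min_cluster_size
        pickfrom <- if (any(ok_big)) which(ok_big) else which(ok)
        counter <- cls[[rest[pickfrom[which.min(dd[pickfrom])]]]]
        symmetric <- TRUE
      } else if (max(anchor$centroid) >= 0.45) {
        # anchor fully clonal in one twin (a = 1 side): the complementary
        # minor lineage is the twin-pure cluster with the largest VAF in
        # the other twin, even when not point-symmetric (the anchor may be
        # a sublineage of an unmarked L1)
        pure <- which.max(anchor$centroid)
        oth <- 3 - pure
        cc <- which(vapply(cls[rest], function(c)
          c$centroid[pure] <= 0.05, logical(1)))
        if (length(cc)) {
          cc_big <- cc[sizes[rest][cc] >= config$min_cluster_size]
          pickfrom <- if (length(cc_big)) cc_big else cc
          u_oth <- vapply(cls[rest][pickfrom], function(c)
            c$centroid[oth], double(1))
          counter <- cls[[rest[pickfrom[which.max(u_oth)]]]]
        }
      }
    }
  } else {
    sub <- which(big & sums < config$anchor_sum_min)
    if (!length(sub)) sub <- which(sums < config$anchor_sum_min)
    if (length(sub)) counter <- cls[[sub[which.max(sums[sub])]]]
  }
  if (is.null(anchor) && is.null(counter))
    stop_arg("anchor fit failure: no usable EEM clusters (n = %d EEMs)",
             nrow(pairs))
  list(anchor = anchor, counter = counter, clusters = cls,
       symmetric = symmetric, anchor_absent = is.null(anchor))
}

#' Estimate the lineage contributions (a, b) from cluster centroids
#'
#' Under the two-lineage model, anchor EEMs sit at VAFs (a/2, b/2) and
#' counter-anchor EEMs at ((1-a)/2, (1-b)/2), so the anchor centroid gives
#' `(a, b) = (2 v1, 2 v2)` and the counter centroid `(1 - 2 u1, 1 - 2 u2)`.
#' With both clusters present the two estimates are averaged with weights
#' proportional to cluster size (inverse-variance weighting under equal
#' per-EEM noise). Estimates are clamped to `[0, 1]` and twins are reordered
#' so that `a >= b` (Twin-1 convention).
#'
#' When the anchor is fully clonal in one twin but the counter cluster is
#' not point-symmetric (the anchor may then be a sublineage of an unmarked
#' L1, which under-reports the co-twin's share), the clonal coordinate is
#' taken from the anchor and the other from the counter — unless the pair's
#' EEMs show no twin-shared detections at all, the para-identical
#' signature, in which case the anchor alone is used.
#'
#' @param anchor,counter clusters from [detect_anchor_clusters()] (either
#'   may be NULL, not both).
#' @param config a [model_config()].
#' @param symmetric TRUE when the counter was found by point symmetry
#'   (see [detect_anchor_clusters()]).
#' @param n_shared_eems number of EEMs detected in both twins (used to
#'   recognise the para-identical signature when `symmetric` is FALSE).
#' @return list: `a`, `b`, `swapped` (TRUE if input twins were reordered),
#'   `source` ("anchor", "counter", "both" or "hybrid").
#' @export
estimate_ab <- function(anchor, counter, config = model_config(),
                        symmetric = TRUE, n_shared_eems = NULL) {
  if (is.null(anchor) && is.null(counter))
    stop_arg("fit failure: both clusters absent")
  if (is.null(anchor)) {
    ab <- 1 - 2 * counter$centroid
    source <- "counter"
  } else if (is.null(counter)) {
    ab <- 2 * anchor$centroid
    source <- "anchor"
  } else if (symmetric) {
    est <- rbind(2 * anchor$centroid, 1 - 2 * counter$centroid)
    w <- c(anchor$size, counter$size)
    ab <- colSums(est * w) / sum(w)
    source <- "both"
  } else if (!is.null(n_shared_eems) && n_shared_eems == 0) {
    ab <- 2 * anchor$centroid           # mutually exclusive EEMs: para-like
    source <- "anchor"
  } else {
    pure <- which.max(anchor$centroid)
    ab <- numeric(2)
    ab[pure] <- 2 * anchor$centroid[pure]
    u_oth <- counter$centroid[3 - pure]
    # counter gives an upper bound on the co-twin share (a deeper L2
    # sublineage under-reports u); the anchor's own co-twin VAF gives a
    # lower bound. A very shallow counter (u < 0.1) is unlikely to be L2
    # itself, so split the difference between the bounds.
    ab[3 - pure] <- if (u_oth >= 0.1) 1 - 2 * u_oth else
      (2 * anchor$centroid[3 - pure] + 1 - 2 * u_oth) / 2
    source <- "hybrid"
  }
  if (!is.null(n_shared_eems) && n_shared_eems == 0)
    ab[which.min(ab)] <- 0  # no twin-shared EEM: no shared lineage signal
  ab <- clamp(unname(ab), 0, 1)
  swapped <- ab[2] > ab[1]
  if (swapped) ab <- rev(ab)
  list(a = ab[1], b = ab[2], swapped = swapped, source = source)
}

#' Classify a twin pair's clonal category from (a, b)
#'
#' para-identical: the twins descend from two independent early lineages
#' (`a = 1, b = 0`); sub-identical: Twin 1 is a clonal subset (`a = 1,
#' 0 < b < 1`); full-identical: both twins are comparable mixtures
#' (`a` close to `b`). Boundaries are softened by `epsilon`; pairs fitting
#' none of the three patterns (mixed but very unequal) are flagged
#' discordant rather than forced into a category.
#'
#' @param a,b lineage contributions with `0 <= b <= a <= 1`.
#' @param epsilon boundary tolerance (default from [model_config()]).
#' @return one of `"para"`, `"sub"`, `"full"`, `"discordant"`.
#' @examples
#' classify_category(1, 0)     # para
#' classify_category(1, 0.6)   # sub
#' classify_category(0.7, 0.6) # full
#' @export
classify_category <- function(a, b, epsilon = model_config()$epsilon) {
  stopifnot(b >= 0, a >= b, a <= 1)
  if (a >= 1 - epsilon && b <= epsilon) return("para")
  if (a >= 1 - epsilon && b > epsilon && b < 1 - epsilon) return("sub")
  if (a < 1 - epsilon && abs(a - b) <= 2 * epsilon) return("full")
  "discordant"
}

#' Fit the two-lineage anchor model to a twin pair
#'
#' Convenience wrapper: cluster detection, (a, b) estimation and category
#' classification in one call.
#'
#' @inheritParams detect_anchor_clusters
#' @param detect_vaf VAF threshold defining a twin-shared EEM detection
#'   for the para-identical signature (default 0.03).
#' @return object of class `anchor_fit`: clusters, `a`, `b`, `swapped`,
#'   `category`, `anchor_absent`, `n_shared_eems`, `epsilon`.
#' @export
fit_anchor_model <- function(pairs, config = model_config(),
                             detect_vaf = 0.03) {
  det <- detect_anchor_clusters(pairs, config)
  ok <- stats::complete.cases(pairs[, c("v1", "v2")])
  n_shared <- sum(pairs$v1[ok] >= detect_vaf & pairs$v2[ok] >= detect_vaf)
  ab <- estimate_ab(det$anchor, det$counter, config,
                    symmetric = det$symmetric, n_shared_eems = n_shared)
  structure(list(anchor = det$anchor, counter = det$counter,
                 clusters = det$clusters, a = ab$a, b = ab$b,
                 swapped = ab$swapped, source = ab$source,
                 n_shared_eems = n_shared,
                 anchor_absent = det$anchor_absent,
                 category = classify_category(ab$a, ab$b, config$epsilon),
                 epsilon = config$epsilon),
            class = "anchor_fit")
}

#' @export
print.anchor_fit <- function(x, ...) {
  cat(sprintf("anchor_fit: a = %.3f, b = %.3f -> %s (%s%s)\n", x$a, x$b,
              x$category, x$source,
              if (x$swapped) ", twins reordered" else ""))
  invisible(x)
}

#' Genetic distance between co-twins
#'
#' Number of EEM events detected in exactly one co-twin.
#'
#' @param calls a `variant_calls` data.frame ([classify_variants()]) for
#'   the pair.
#' @return non-negative integer.
#' @export
genetic_distance <- function(calls) {
  stopifnot(inherits(calls, "variant_calls"))
  sum(calls$class == "eem" & calls$n_detected == 1)
}

#' Cell divisions separating twin founder cells
#'
#' Converts a count of lineage-unique clonal mutations into cell divisions
#' using the clock-like early embryonic mutation rate.
#'
#' @param n_unique_clonal number of clonal mutations unique to one lineage.
#' @param founder_rate mutations per cell per division (default 1.2).
#' @param mode `"nearest"` (rounded estimate) or `"floor"` (for "at least
#'   n divisions" statements).
#' @return integer number of divisions.
#' @examples
#' divisions_between_founders(6, 1.2)             # 5
#' divisions_between_founders(5, 1.2, "floor")    # 4
#' @export
divisions_between_founders <- function(n_unique_clonal, founder_rate = 1.2,
                                       mode = c("nearest", "floor")) {
  if (n_unique_clonal < 0) stop_arg("n_unique_clonal must be >= 0")
  mode <- match.arg(mode)
  d <- n_unique_clonal / founder_rate
  as.integer(if (mode == "nearest") round(d) else floor(d))
}

#' EEM VAF pairs for a twin pair from a variant table
#'
#' @param table a `variant_table` (typically deep-targeted).
#' @param calls `variant_calls` used to restrict to EEM class.
#' @param samples length-2 character: the Twin 1 and Twin 2 samples.
#' @param clonal_both_max EEMs with VAF at or above this in *both* twins
#'   are dropped (default 0.4): a mutation fully clonal in both twins is
#'   indistinguishable from a de novo variant and carries no lineage
#'   information for the two-lineage fit.
#' @return data.frame (variant, v1, v2) suitable for
#'   [detect_anchor_clusters()]; missing VAFs are treated as 0 when the
#'   variant is detected in the co-twin.
#' @export
eem_vaf_pairs <- function(table, calls, samples, clonal_both_max = 0.4) {
  stopifnot(length(samples) == 2)
  v <- vaf_matrix(table)[, samples, drop = FALSE]
  keep <- as.character(calls$variant[calls$class == "eem"])
  keep <- intersect(keep, rownames(v))
  v <- v[keep, , drop = FALSE]
  out <- data.frame(variant = rownames(v),
                    v1 = ifelse(is.na(v[, 1]), 0, v[, 1]),
                    v2 = ifelse(is.na(v[, 2]), 0, v[, 2]),
                    stringsAsFactors = FALSE)
  out[!(out$v1 >= clonal_both_max & out$v2 >= clonal_both_max), ]
}
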