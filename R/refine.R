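#' Refine EEM clusters with multi-tissue VAF profiles
#'
#' With three or more samples per pair (buccal, cord blood, placental
#' patches, umbilical cord ...), EEMs are clustered on their VAF profile
#' across all samples (correlation distance, average linkage), which
#' separates lineages that are indistinguishable in two-sample VAF space.
#' Clusters are then ordered into a nesting-consistent lineage by
#' containment of their detection patterns: cluster A is ancestral to B
#' when A is detected in a strict superset of B's samples (ties broken by
#' mean VAF), and the hierarchy is serialised as a Newick string of named
#' clusters.
#'
#' @param vafs numeric matrix, EEMs x samples (at least 3 samples).
#' @param cut_height correlation-distance cut for cluster membership
#'   (default 0.15, calibrated to the binomial VAF noise at shallow
#'   placental-patch depths; nested lineage profiles stay correlated at
#'   roughly 0.7, i.e. distance 0.3, so the cut must sit well below that).
#' @param detect_vaf VAF at or above which an EEM counts as detected in a
#'   sample (default 0.03).
#' @return list: `cluster` (named integer vector EEM -> cluster),
#'   `clusters` (per-cluster members, detection pattern, mean VAF),
#'   `edges` (parent-child data.frame over cluster ids, parent 0 = root),
#'   `newick`.
#' @export
multisample_refine <- function(vafs, cut_height = 0.15, detect_vaf = 0.03) {
  if (is.null(dim(vafs)) || ncol(vafs) < 3)
    stop_arg("multi-sample refinement needs >= 3 samples; use the two-sample anchor fit instead")
  vafs[is.na(vafs)] <- 0
  if (is.null(rownames(vafs))) rownames(vafs) <- paste0("e", seq_len(nrow(vafs)))
  sds <- apply(vafs, 1, stats::sd)
  cl <- integer(nrow(vafs))
  varying <- which(sds > 0)
  if (length(varying) > 1) {
    d <- stats::as.dist(1 - stats::cor(t(vafs[varying, , drop = FALSE])))
    d[is.na(d)] <- 2
    cl[varying] <- stats::cutree(stats::hclust(d, "average"),
                                 h = cut_height)
  } else if (length(varying) == 1) cl[varying] <- 1L
  # constant-profile EEMs: group by identical rounded profile
  flat <- which(sds == 0)
  if (length(flat)) {
    key <- apply(round(vafs[flat, , drop = FALSE], 6), 1, paste,
                 collapse = ",")
    cl[flat] <- max(cl) + as.integer(factor(key, levels = unique(key)))
  }
  names(cl) <- rownames(vafs)
  ids <- sort(unique(cl))
  clusters <- lapply(ids, function(k) {
    rows <- vafs[cl == k, , drop = FALSE]
    prof <- colMeans(rows)
    list(id = k, members = rownames(rows), size = nrow(rows),
         profile = prof, pattern = prof >= detect_vaf,
         mean_vaf = mean(prof))
  })
  names(clusters) <- paste0("C", ids)
  # containment partial order -> parent = smallest strict super-pattern
  npat <- vapply(clusters, function(c) sum(c$pattern), integer(1))
  parent <- integer(length(clusters))
  for (i in seq_along(clusters)) {
    sup <- which(vapply(seq_along(clusters), function(j) {
      j != i && all(clusters[[j]]$pattern | !clusters[[i]]$pattern) &&
        (npat[j] > npat[i] ||
           (npat[j] == npat[i] &&
              clusters[[j]]$mean_vaf > clusters[[i]]$mean_vaf))
    }, logical(1)))
    parent[i] <- if (length(sup)) sup[which.min(npat[sup])] else 0L
  }
  edges <- data.frame(parent = parent, child = seq_along(clusters))
  nwk <- function(i) {
    kids <- which(parent == i)
    lab <- if (i == 0) "root" else names(clusters)[i]
    if (!length(kids)) return(lab)
    paste0("(", paste(vapply(kids, nwk, character(1)), collapse = ","),
           ")", lab)
  }
  list(cluster = cl, clusters = clusters, edges = edges,
       newick = paste0(nwk(0L), ";"))
}

#' Order a monozygotic triplet's founders from pairwise fits
#'
#' The pair with the most shared clonal EEMs is joined first (latest shared
#' ancestor); nesting direction follows which individual is the pure
#' (`a = 1`) member of each sub-identical pair. Three mutually
#' para-identical pairs give a star (no nesting evidence); conflicting
#' nesting is flagged unresolvable rather than silently guessed.
#'
#' @param fits named list of three `anchor_fit` objects, names
#'   `"<A>-<B>"` over individuals A, B.
#' @param shared_clonal named integer vector (same names): shared clonal
#'   EEM counts per pair.
#' @return list: `newick`, `resolved` (logical), `reason`.
#' @export
triplet_topology <- function(fits, shared_clonal) {
  stopifnot(length(fits) == 3, identical(sort(names(fits)),
                                         sort(names(shared_clonal))))
  members <- strsplit(names(fits), "-", fixed = TRUE)
  inds <- unique(unlist(members))
  if (length(inds) != 3) stop_arg("fits must cover 3 individuals pairwise")
  cats <- vapply(fits, `[[`, character(1), "category")
  if (all(cats == "para"))
    return(list(newick = paste0("(", paste(inds, collapse = ","), ");"),
                resolved = FALSE, reason = "star: three para pairs"))
  first <- which.max(shared_clonal)
  joined <- members[[first]]
  out <- setdiff(inds, joined)
  # consistency: in each pair containing the outgroup individual, the
  # outgroup must not be the nested (b-side, impure) member of a sub pair
  # in a way that contradicts joining `joined` first
  ok <- TRUE
  for (i in setdiff(seq_len(3), first)) {
    if (cats[i] %in% c("sub")) {
      # pure member (a = 1 side) of this pair is its Twin 1 after ordering;
      # we only know order via `swapped` relative to input naming
      pure <- if (fits[[i]]$swapped) members[[i]][2] else members[[i]][1]
      # if the outgroup is the nested member of both cross pairs while the
      # joined pair shares least, nesting is contradictory
      if (!(pure %in% c(out, joined))) ok <- FALSE
    }
  }
  if (min(shared_clonal[-first]) > shared_clonal[first])
    ok <- FALSE
  if (!ok)
    return(list(newick = NA_character_, resolved = FALSE,
                reason = "inconsistent pairwise nesting"))
  list(newick = sprintf("((%s,%s),%s);", joined[1], joined[2], out),
       resolved = TRUE, reason = "ok")
}

#' Count shared clonal EEMs for each pair of individuals
#'
#' A variant counts as shared clonal for a pair when its VAF is at or above
#' `clonal_min_vaf` in both individuals' samples but it is not clonal in
#' every individual (fully clonal variants carry no branching information).
#'
#' @param vafs matrix variants x individuals (one sample per individual).
#' @param clonal_min_vaf clonality threshold (default 0.4).
#' @return named integer vector over pairs `"<A>-<B>"`.
#' @export
shared_clonal_counts <- function(vafs, clonal_min_vaf = 0.4) {
  stopifnot(ncol(vafs) >= 2)
  cl <- !is.na(vafs) & vafs >= clonal_min_vaf
  informative <- rowSums(cl) < ncol(vafs)
  combs <- utils::combn(colnames(vafs), 2)
  out <- apply(combs, 2, function(p)
    sum(cl[informative, p[1]] & cl[informative, p[2]]))
  stats::setNames(as.integer(out), apply(combs, 2, paste, collapse = "-"))
}
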