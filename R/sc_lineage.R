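#' Single-cell observation likelihood under the dropout model
#'
#' P(missing | any genotype) = locus dropout; conditional on coverage, a
#' true alt is observed alt with probability `1 - ado_rate` and ref
#' otherwise, and a true ref is observed alt with probability `fp_rate`.
#' Rows sum to 1 over \{ref, alt, missing\} for each true genotype.
#'
#' @param observed observed state: 0 (ref), 1 (alt) or NA (missing);
#'   vectorised.
#' @param genotype true genotype: 0 or 1; vectorised.
#' @param sc an [sc_params()].
#' @return probability vector.
#' @examples
#' observation_likelihood(NA, 1, sc_params(0.23, 0.46))      # 0.46
#' observation_likelihood(1, 1, sc_params(0.23, 0.46))       # 0.4158
#' @export
observation_likelihood <- function(observed, genotype, sc = sc_params()) {
  lam <- sc$locus_dropout; ado <- sc$ado_rate; fp <- sc$fp_rate
  n <- max(length(observed), length(genotype))
  observed <- rep_len(observed, n); genotype <- rep_len(genotype, n)
  ifelse(is.na(observed), lam,
         ifelse(genotype == 1,
                ifelse(observed == 1, (1 - lam) * (1 - ado),
                       (1 - lam) * ado),
                ifelse(observed == 1, (1 - lam) * fp,
                       (1 - lam) * (1 - fp))))
}

# log-likelihood of a cell's observations given clade marker model:
# alt at `alt_markers`, ref at `ref_markers`
.cell_clade_loglik <- function(obs, alt_markers, ref_markers, sc) {
  sum(log(observation_likelihood(obs[alt_markers], 1L, sc))) +
    sum(log(observation_likelihood(obs[ref_markers], 0L, sc)))
}

# is a variant pair mutually exclusive? observed co-occurrence must not
# exceed the 99th percentile expected from false positives alone
.mutually_exclusive <- function(x, y, fp_obs) {
  co <- sum(x == 1 & y == 1, na.rm = TRUE)
  thr <- max(stats::qbinom(0.99, sum(x == 1, na.rm = TRUE), fp_obs),
             stats::qbinom(0.99, sum(y == 1, na.rm = TRUE), fp_obs))
  co <= thr
}

# split variants into the two most prevalent mutually exclusive groups
.find_marker_groups <- function(mat, sc) {
  prev <- colSums(mat == 1, na.rm = TRUE)
  vars <- colnames(mat)[prev > 0]
  if (length(vars) < 2) return(NULL)
  m <- mat[, vars, drop = FALSE]
  if (length(vars) == 2) {
    g <- list(vars[1], vars[2])
  } else {
    present <- (m == 1) & !is.na(m)
    d <- stats::dist(t(present), method = "binary")  # Jaccard distance
    g <- split(vars, stats::cutree(stats::hclust(d, "average"), k = 2))
  }
  fp_obs <- (1 - sc$locus_dropout) * sc$fp_rate
  x <- rowSums(m[, g[[1]], drop = FALSE] == 1, na.rm = TRUE) > 0
  y <- rowSums(m[, g[[2]], drop = FALSE] == 1, na.rm = TRUE) > 0
  # group-level false-positive rate: any of the k opposite markers flips
  fp_any <- function(k) 1 - (1 - fp_obs)^k
  co <- sum(x & y)
  thr <- max(stats::qbinom(0.99, sum(x), fp_any(length(g[[2]]))),
             stats::qbinom(0.99, sum(y), fp_any(length(g[[1]]))))
  if (co > thr) return(NULL)
  g
}

#' Reconstruct an early-lineage phylogeny from single-cell genotypes
#'
#' Greedy top-down clade assignment: the two top clades are seeded with the
#' anchor and counter-anchor EEM marker sets (or, without a bulk fit, the
#' two most prevalent mutually exclusive variant groups). Each cell is
#' assigned to the clade maximising its summed log observation likelihood
#' (alt at the clade's markers, ref at the sibling clade's); cells whose
#' score gap is below 1 log unit are labelled ambiguous, with exact ties
#' broken toward the clade with more covered marker sites. Putative markers
#' that co-occur with the opposite clade's markers beyond what false
#' positives explain are reassigned downstream (dropped from the top split).
#' The procedure recurses inside each clade on the remaining variants.
#'
#' @param mat an `sc_genotype_matrix` (cells x variants, 0/1/NA).
#' @param markers optional list of two character vectors of variant names
#'   (anchor, counter-anchor) seeding the top clades.
#' @param sc an [sc_params()] (defaults to the matrix's attached params).
#' @param min_cells minimum clade size to recurse into (default 4).
#' @param max_depth recursion depth (default 3).
#' @return object of class `sc_phylogeny`: `assignment` (factor per cell,
#'   clade path labels like "L1/L1.1", or "ambiguous"), `score` (per-cell
#'   log-likelihood gap), `clades` (marker sets per clade), `newick`.
#' @export
reconstruct_sc_phylogeny <- function(mat, markers = NULL, sc = NULL,
                                     min_cells = 4, max_depth = 3) {
  sc <- sc %||% attr(mat, "sc_params") %||% sc_params()
  if (nrow(mat) < 2 || ncol(mat) < 1)
    stop_arg("need >= 2 cells and >= 1 variant")
  if (all(is.na(mat)))
    return(structure(list(status = "failed: all entries missing",
                          assignment = NULL), class = "sc_phylogeny"))
  clades <- list()
  assignment <- rep(NA_character_, nrow(mat))
  gap <- rep(NA_real_, nrow(mat))
  fp_obs <- (1 - sc$locus_dropout) * sc$fp_rate

  split_cells <- function(cells, vars, prefix, depth, seed_markers) {
    m <- mat[cells, vars, drop = FALSE]
    groups <- if (!is.null(seed_markers)) {
      lapply(seed_markers, intersect, y = vars)
    } else .find_marker_groups(m, sc)
    if (is.null(groups) || !length(groups[[1]]) || !length(groups[[2]]))
      return(invisible(NULL))
    # purge markers co-occurring with the opposite group (downstream EEMs
    # misplaced by the bulk fit): a genuine clade marker is pairwise
    # mutually exclusive with most of the opposite clade's markers, a
    # misplaced one with few or none
    purge <- function(g, opp) {
      frac_excl <- vapply(g, function(v)
        mean(vapply(opp, function(w)
          .mutually_exclusive(m[, v], m[, w], fp_obs), logical(1))),
        double(1))
      g[frac_excl >= 0.5]
    }
    g1 <- purge(groups[[1]], groups[[2]])
    g2 <- purge(groups[[2]], groups[[1]])
    if (!length(g1) || !length(g2)) { g1 <- groups[[1]]; g2 <- groups[[2]] }
    lab <- paste0(prefix, c("1", "2"))
    clades[[lab[1]]] <<- g1
    clades[[lab[2]]] <<- g2
    s1 <- apply(m, 1, .cell_clade_loglik, alt_markers = g1,
                ref_markers = g2, sc = sc)
    s2 <- apply(m, 1, .cell_clade_loglik, alt_markers = g2,
                ref_markers = g1, sc = sc)
    d <- s1 - s2
    obs1 <- rowSums(!is.na(m[, g1, drop = FALSE]))
    obs2 <- rowSums(!is.na(m[, g2, drop = FALSE]))
    pick <- ifelse(abs(d) < 1e-9,
                   ifelse(obs1 > obs2, 1L, ifelse(obs2 > obs1, 2L, 0L)),
                   ifelse(d >= 1, 1L, ifelse(d <= -1, 2L, 0L)))
    assignment[cells] <<- ifelse(pick == 1L, lab[1],
                                 ifelse(pick == 2L, lab[2], "ambiguous"))
    gap[cells] <<- abs(d)
    if (depth < max_depth) {
      rest <- setdiff(vars, c(g1, g2))
      for (k in 1:2) {
        sub <- cells[pick == k]
        if (length(sub) >= min_cells && length(rest) >= 2)
          split_cells(sub, rest, paste0(lab[k], "."), depth + 1, NULL)
      }
    }
    invisible(NULL)
  }
  top_markers <- if (!is.null(markers))
    list(intersect(markers[[1]], colnames(mat)),
         intersect(markers[[2]], colnames(mat))) else NULL
  split_cells(seq_len(nrow(mat)), colnames(mat), "L", 1, top_markers)
  if (!length(clades))
    return(structure(list(status = "failed: no mutually exclusive markers",
                          assignment = NULL), class = "sc_phylogeny"))
  # Newick over the clade hierarchy: children of p are "p.<k>"
  children_of <- function(p) {
    pre <- paste0(p, ".")
    names(clades)[startsWith(names(clades), pre) &
                    !grepl(".", substring(names(clades), nchar(pre) + 1),
                           fixed = TRUE)]
  }
  nwk <- function(p) {
    kids <- children_of(p)
    if (!length(kids)) return(p)
    paste0("(", paste(vapply(kids, nwk, character(1)), collapse = ","),
           ")", p)
  }
  top <- intersect(c("L1", "L2"), names(clades))
  structure(list(status = "ok",
                 assignment = stats::setNames(assignment, rownames(mat)),
                 score = stats::setNames(gap, rownames(mat)),
                 clades = clades,
                 newick = paste0("(", paste(vapply(top, nwk, character(1)),
                                            collapse = ","), ");")),
            class = "sc_phylogeny")
}

#' @export
print.sc_phylogeny <- function(x, ...) {
  if (!identical(x$status, "ok")) {
    cat("sc_phylogeny:", x$status, "\n")
  } else {
    cat("sc_phylogeny:", x$newick, "\n")
    print(table(x$assignment))
  }
  invisible(x)
}

#' Per-twin lineage contributions from single-cell assignments
#'
#' Fraction of each twin's cells assigned to each top-level clade, with
#' exact binomial 95% CIs, for comparison against the bulk-derived a/2 and
#' b/2 expectations.
#'
#' @param phylo an `sc_phylogeny`.
#' @param cell_twin individual label per cell (defaults to the matrix
#'   attribute carried through `names(phylo$assignment)` order).
#' @return data.frame: individual, clade, n, total (assigned cells),
#'   fraction, ci_lo, ci_hi.
#' @export
lineage_contribution <- function(phylo, cell_twin) {
  if (!identical(phylo$status, "ok")) stop_arg("phylogeny not reconstructed")
  keep <- phylo$assignment != "ambiguous" & !is.na(phylo$assignment)
  top <- sub("^(L[12]).*", "\\1", phylo$assignment)
  out <- do.call(rbind, lapply(unique(cell_twin), function(ind) {
    sel <- keep & cell_twin == ind
    tot <- sum(sel)
    do.call(rbind, lapply(c("L1", "L2"), function(cl) {
      n <- sum(top[sel] == cl)
      ci <- if (tot > 0) stats::binom.test(n, tot)$conf.int else c(NA, NA)
      data.frame(individual = ind, clade = cl, n = n, total = tot,
                 fraction = if (tot > 0) n / tot else NA_real_,
                 ci_lo = ci[1], ci_hi = ci[2])
    }))
  }))
  rownames(out) <- NULL
  out
}
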