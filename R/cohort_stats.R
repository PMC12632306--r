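#' Fisher's exact test for a 2x2 table
#'
#' Full hypergeometric enumeration with both margins fixed. The two-sided
#' p-value follows the probability-mass rule: the sum of probabilities of
#' all tables no more probable than the observed one (within 1e-7 relative
#' slack); `alternative = "doubled"` instead doubles the smaller one-tailed
#' mass (capped at 1), since published two-sided conventions differ.
#'
#' @param tab 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   counts.
#' @param alternative `"mass"` (default) or `"doubled"`.
#' @return object of class `test_result`: statistic (observed table
#'   probability), p.value, method.
#' @examples
#' fisher_exact_2x2(matrix(c(7, 2, 1, 12), 2))$p.value  # 0.00149
#' @export
fisher_exact_2x2 <- function(tab, alternative = c("mass", "doubled")) {
  alternative <- match.arg(alternative)
  if (!is.matrix(tab)) tab <- matrix(tab, 2, 2, byrow = TRUE)
  if (any(tab < 0)) stop_arg("table entries must be non-negative")
  if (sum(tab) == 0) stop_arg("table total must be positive")
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  p <- if (alternative == "mass") {
    sum(pr[pr <= p_obs * (1 + 1e-7)])
  } else {
    lower <- sum(pr[x <= tab[1, 1]])
    upper <- sum(pr[x >= tab[1, 1]])
    min(1, 2 * min(lower, upper))
  }
  structure(list(statistic = p_obs, p.value = min(p, 1),
                 method = paste0("Fisher exact 2x2 (", alternative, ")"),
                 table = tab),
            class = "test_result")
}

# log null probability of an r x c table with fixed margins
.table_log_prob <- function(x, row_margin, col_margin) {
  sum(lgamma(row_margin + 1)) + sum(lgamma(col_margin + 1)) -
    lgamma(sum(row_margin) + 1) - sum(lgamma(x + 1))
}

#' Sample contingency tables with both margins fixed
#'
#' Sequential hypergeometric fill, vectorised over draws: cells are filled
#' row by row, each count drawn from the hypergeometric distribution given
#' the remaining row and column totals.
#'
#' @param B number of tables.
#' @param row_margin,col_margin margin totals.
#' @return integer matrix B x (r*c), tables in row-major cell order.
#' @keywords internal
sample_fixed_margin_tables <- function(B, row_margin, col_margin) {
  R <- length(row_margin); C <- length(col_margin)
  colrem <- matrix(rep(col_margin, each = B), B, C)
  out <- matrix(0L, B, R * C)
  for (i in seq_len(R)) {
    rowrem <- rep(row_margin[i], B)
    for (j in seq_len(C - 1)) {
      other <- if (j + 1 <= C)
        rowSums(colrem[, (j + 1):C, drop = FALSE]) else 0
      x <- stats::rhyper(B, m = colrem[, j], n = other, k = rowrem)
      out[, (i - 1) * C + j] <- x
      colrem[, j] <- colrem[, j] - x
      rowrem <- rowrem - x
    }
    out[, i * C] <- rowrem
    colrem[, C] <- colrem[, C] - rowrem
  }
  out
}

#' Monte Carlo Fisher test for an r x c table
#'
#' Samples `B` tables with both margins fixed and estimates the two-sided
#' p-value as the fraction of tables no more probable than the observed one
#' under the multivariate hypergeometric null, with the add-one estimator
#' `(1 + x) / (B + 1)` so p is never exactly zero.
#'
#' @param tab r x c matrix of non-negative counts (rows/columns that are
#'   entirely zero are dropped with a warning).
#' @param B number of Monte Carlo tables (>= 1000).
#' @param seed integer seed.
#' @return `test_result` with p.value, B and seed.
#' @export
fisher_montecarlo <- function(tab, B = 10000, seed = 1) {
  if (!is.matrix(tab) || any(tab < 0)) stop_arg("tab must be a non-negative matrix")
  if (B < 1000) stop_arg("B must be >= 1000")
  zr <- rowSums(tab) == 0; zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warning("dropping all-zero margins from the table")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop_arg("need at least a 2x2 table after margin reduction")
  rm <- rowSums(tab); cm <- colSums(tab)
  lp_obs <- .table_log_prob(as.vector(t(tab)), rm, cm)
  with_seed(seed, {
    samp <- sample_fixed_margin_tables(B, rm, cm)
    lp <- sum(lgamma(rm + 1)) + sum(lgamma(cm + 1)) -
      lgamma(sum(rm) + 1) - rowSums(lgamma(samp + 1))
    x <- sum(lp <= lp_obs + 1e-7)
    structure(list(statistic = lp_obs,
                   p.value = (1 + x) / (B + 1),
                   method = "Fisher r x c, Monte Carlo (fixed margins)",
                   B = B, seed = seed, table = tab),
              class = "test_result")
  })
}

#' Kruskal-Wallis test with Bonferroni-corrected pairwise comparisons
#'
#' Rank-sum H statistic with tie correction and a chi-square reference
#' distribution on k - 1 degrees of freedom, plus optional pairwise
#' two-group tests corrected by multiplying each p by the number of
#' comparisons (capped at 1).
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @param pairwise if TRUE, run all pairwise two-group comparisons.
#' @return `test_result` with statistic `H`, df, p.value, `all_ties` flag,
#'   and (when requested) a `pairwise` data.frame with raw and adjusted p.
#' @examples
#' kruskal_wallis_bonferroni(list(1:3, 4:6, 7:9))$statistic  # 7.2
#' @export
kruskal_wallis_bonferroni <- function(groups, pairwise = FALSE) {
  if (length(groups) < 2) stop_arg("need >= 2 groups")
  if (any(!vapply(groups, length, integer(1))))
    stop_arg("every group needs at least one observation")
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  Rs <- tapply(r, g, sum)
  H <- 12 / (N * (N + 1)) * sum(Rs^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(x)
  Cf <- 1 - sum(ties^3 - ties) / (N^3 - N)
  all_ties <- Cf == 0
  H <- if (all_ties) 0 else H / Cf
  df <- length(groups) - 1
  p <- if (all_ties) 1 else stats::pchisq(H, df, lower.tail = FALSE)
  pw <- NULL
  if (pairwise) {
    combs <- utils::combn(length(groups), 2)
    m <- ncol(combs)
    pw <- do.call(rbind, lapply(seq_len(m), function(i) {
      sub <- kruskal_wallis_bonferroni(groups[combs[, i]])
      data.frame(group1 = combs[1, i], group2 = combs[2, i],
                 H = sub$statistic, p = sub$p.value,
                 p_adjusted = min(1, m * sub$p.value))
    }))
  }
  structure(list(statistic = H, df = df, p.value = p,
                 all_ties = all_ties,
                 method = "Kruskal-Wallis (tie-corrected)",
                 pairwise = pw),
            class = "test_result")
}

#' Bonferroni adjustment
#'
#' @param p raw p-value(s).
#' @param m number of comparisons.
#' @return `min(1, m * p)`, vectorised.
#' @export
bonferroni <- function(p, m) pmin(1, m * p)

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method,
              x$statistic, x$p.value))
  if (!is.null(x$pairwise)) print(x$pairwise, row.names = FALSE)
  invisible(x)
}
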