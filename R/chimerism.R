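#' Select twin-unique clonal EEMs informative for blood chimerism
#'
#' An EEM is informative when it is clonal in exactly one twin's buccal
#' tissue (VAF at or above `clonal_min_vaf`) and essentially absent from
#' the co-twin's (VAF at or below `absent_max_vaf`); such mutations mark one
#' twin's whole soma, so their cord-blood VAF reads out that twin's share
#' of a mixed hematopoietic pool. Full-identical pairs typically yield an
#' empty list.
#'
#' @param table a `variant_table` with buccal VAFs for both twins
#'   (deep-targeted counts preferred).
#' @param calls `variant_calls` restricting to EEM class.
#' @param buccal_samples length-2 character, Twin 1 and Twin 2 buccal
#'   samples (order defines source twin 1/2).
#' @param clonal_min_vaf clonality threshold (default 0.4).
#' @param absent_max_vaf co-twin absence threshold (default 0.02).
#' @return data.frame (variant, source_twin in 1/2); zero rows is a valid
#'   result.
#' @export
select_informative <- function(table, calls, buccal_samples,
                               clonal_min_vaf = 0.4,
                               absent_max_vaf = 0.02) {
  stopifnot(length(buccal_samples) == 2)
  v <- vaf_matrix(table)[, buccal_samples, drop = FALSE]
  eems <- intersect(as.character(calls$variant[calls$class == "eem"]),
                    rownames(v))
  v <- v[eems, , drop = FALSE]
  src1 <- !is.na(v[, 1]) & v[, 1] >= clonal_min_vaf &
    !is.na(v[, 2]) & v[, 2] <= absent_max_vaf
  src2 <- !is.na(v[, 2]) & v[, 2] >= clonal_min_vaf &
    !is.na(v[, 1]) & v[, 1] <= absent_max_vaf
  data.frame(variant = c(rownames(v)[src1], rownames(v)[src2]),
             source_twin = rep(1:2, c(sum(src1), sum(src2))),
             stringsAsFactors = FALSE)
}

# binomial log-likelihood of cord-blood counts at twin-2-lineage fraction m
.mix_loglik <- function(m, alt, depth, source_twin, err) {
  ev <- ifelse(source_twin == 2, m / 2, (1 - m) / 2)
  ev <- clamp(ev, err, 0.5)
  sum(stats::dbinom(alt, depth, ev, log = TRUE))
}

#' Maximum-likelihood cord-blood mixing fraction
#'
#' For each cord-blood sample, models the expected VAF of a source-twin-s
#' informative EEM as half that twin's lineage fraction of the sample's
#' cells and maximises the binomial read-count likelihood over the
#' twin-2-lineage fraction `m` on a 1e-3 grid followed by golden-section
#' refinement; the 95% CI is the profile-likelihood interval
#' (drop of 1.92 log units).
#'
#' @param informative data.frame from [select_informative()].
#' @param counts a `variant_table` holding the cord-blood read counts
#'   (typically deep-targeted).
#' @param cord_samples character vector of cord-blood sample names.
#' @param seq_error per-base error rate; the error floor `seq_error / 3`
#'   keeps zero-VAF observations finite.
#' @param pool if TRUE, fit one shared `m` across all cord samples instead
#'   of one per sample.
#' @return object of class `mixing_estimate`: per-sample rows with `m`
#'   (fraction from Twin 2's lineage), `major` = max(m, 1-m), CI bounds,
#'   log-likelihood and the number of informative EEMs; or a single pooled
#'   row. Status `"undefined"` with zero informative EEMs.
#' @export
estimate_mixing <- function(informative, counts, cord_samples,
                            seq_error = 0.001, pool = FALSE) {
  if (nrow(informative) == 0)
    return(structure(list(status = "undefined", estimates = NULL),
                     class = "mixing_estimate"))
  err <- seq_error / 3
  dp <- vaf_matrix(counts, "depth")
  ad <- vaf_matrix(counts, "alt")
  idx <- match(informative$variant, rownames(dp))
  if (anyNA(idx)) stop_arg("informative EEMs missing from count table")
  fit_one <- function(samples) {
    alt <- as.vector(ad[idx, samples])
    depth <- as.vector(dp[idx, samples])
    st <- rep(informative$source_twin, times = length(samples))
    keep <- !is.na(depth) & depth > 0
    if (!any(keep)) return(NULL)
    alt <- alt[keep]; depth <- depth[keep]; st <- st[keep]
    grid <- seq(0, 1, by = 1e-3)
    ll <- vapply(grid, .mix_loglik, double(1), alt, depth, st, err)
    i <- which.max(ll)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(.mix_loglik, c(lo, hi), alt = alt,
                           depth = depth, source_twin = st, err = err,
                           maximum = TRUE, tol = 1e-7)
    inside <- ll >= opt$objective - 1.92
    ci <- range(grid[inside])
    data.frame(m = opt$maximum, major = max(opt$maximum, 1 - opt$maximum),
               ci_lo = ci[1], ci_hi = ci[2], loglik = opt$objective,
               n_informative = nrow(informative))
  }
  est <- if (pool) {
    cbind(sample = "pooled", fit_one(cord_samples))
  } else {
    do.call(rbind, lapply(cord_samples, function(s) {
      r <- fit_one(s)
      if (is.null(r)) NULL else cbind(sample = s, r)
    }))
  }
  structure(list(status = "ok", estimates = est),
            class = "mixing_estimate")
}

#' @export
print.mixing_estimate <- function(x, ...) {
  if (x$status != "ok") {
    cat("mixing_estimate: undefined (no informative EEMs)\n")
  } else {
    cat("mixing_estimate (m = fraction from Twin 2 lineage):\n")
    print(x$estimates, row.names = FALSE)
  }
  invisible(x)
}
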