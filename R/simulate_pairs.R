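#' Simulate EEM VAF pairs directly from the two-lineage model
#'
#' Generates the deep-targeted readout of a twin pair with lineage
#' contributions `(a, b)`: `n_anchor` EEMs at true VAFs `(a/2, b/2)`,
#' `n_counter` at `((1-a)/2, (1-b)/2)`, and `n_background` EEMs on random
#' sublineages (a random parent lineage, halved per extra generation with
#' mild jitter), all read with Poisson depth and binomial alt counts. This
#' is the right granularity for testing cluster detection and (a, b)
#' recovery without the tissue-bottleneck layer of the full embryo
#' simulation.
#'
#' @param a,b lineage contributions, `a + b >= 1` (L1 dominant).
#' @param n_anchor,n_counter,n_background EEM counts per compartment.
#' @param depth mean read depth (default 700).
#' @param seq_error per-base error rate (default 0.001).
#' @param seed optional integer seed.
#' @return data.frame (variant, v1, v2) of observed VAFs, with the true
#'   cluster of each EEM in attribute `truth`.
#' @export
simulate_vaf_pairs <- function(a, b, n_anchor = 12, n_counter = 12,
                               n_background = 15, depth = 700,
                               seq_error = 0.001, seed = NULL) {
  stopifnot(a >= 0, a <= 1, b >= 0, b <= 1)
  with_seed(seed, {
    ev <- model_expected_vafs(a, b)
    tv <- rbind(
      matrix(rep(ev$anchor, each = n_anchor), ncol = 2),
      matrix(rep(ev$counter, each = n_counter), ncol = 2))
    truth <- c(rep("anchor", n_anchor), rep("counter", n_counter))
    if (n_background > 0) {
      par <- sample(0:1, n_background, replace = TRUE)
      gen <- sample(1:2, n_background, replace = TRUE)
      jit <- stats::runif(n_background, 0.7, 1.3)
      share <- 0.5^gen * jit
      bg <- cbind(ifelse(par == 0, ev$anchor[1], ev$counter[1]),
                  ifelse(par == 0, ev$anchor[2], ev$counter[2])) * share
      tv <- rbind(tv, bg)
      truth <- c(truth, rep("background", n_background))
    }
    e <- seq_error
    dp <- matrix(stats::rpois(length(tv), depth), ncol = 2)
    p <- tv * (1 - e) + (1 - tv) * e / 3
    alt <- matrix(stats::rbinom(length(tv), dp, p), ncol = 2)
    out <- data.frame(variant = paste0("e", seq_len(nrow(tv))),
                      v1 = ifelse(dp[, 1] > 0, alt[, 1] / dp[, 1], 0),
                      v2 = ifelse(dp[, 2] > 0, alt[, 2] / dp[, 2], 0),
                      stringsAsFactors = FALSE)
    attr(out, "truth") <- truth
    out
  })
}

#' Simulate informative-EEM cord-blood read counts for a mixing fraction
#'
#' Twin-unique clonal EEMs read out a mixed hematopoietic pool: a
#' source-twin-1 EEM has expected cord-blood VAF `(1 - m) / 2` and a
#' source-twin-2 EEM `m / 2`, where `m` is the twin-2-lineage fraction.
#'
#' @param m twin-2-lineage fraction of the pool, in `[0, 1]`.
#' @param n1,n2 numbers of informative EEMs unique to Twin 1 and Twin 2.
#' @param depth mean read depth (default 700).
#' @param n_samples number of cord-blood samples sharing the pool
#'   (default 2).
#' @param seq_error per-base error rate.
#' @param seed optional integer seed.
#' @return list: `informative` data.frame (variant, source_twin), `counts`
#'   `variant_table` with samples `cord1`, `cord2`, ...
#' @export
simulate_mixing_counts <- function(m, n1 = 4, n2 = 4, depth = 700,
                                   n_samples = 2, seq_error = 0.001,
                                   seed = NULL) {
  stopifnot(m >= 0, m <= 1, n1 + n2 >= 1)
  with_seed(seed, {
    src <- rep(1:2, c(n1, n2))
    vid <- paste0("u", seq_along(src))
    ev <- ifelse(src == 2, m / 2, (1 - m) / 2)
    e <- seq_error
    rows <- do.call(rbind, lapply(seq_len(n_samples), function(s) {
      dp <- stats::rpois(length(ev), depth)
      alt <- stats::rbinom(length(ev), dp, ev * (1 - e) + (1 - ev) * e / 3)
      data.frame(family = "SIM", variant = vid,
                 sample = paste0("cord", s), depth = dp, alt = alt,
                 stringsAsFactors = FALSE)
    }))
    list(informative = data.frame(variant = vid, source_twin = src,
                                  stringsAsFactors = FALSE),
         counts = variant_table(rows))
  })
}
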