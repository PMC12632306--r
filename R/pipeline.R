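#' Analyse one simulated family
#'
#' Calls variants from the 60x table, validates candidates by simulated
#' deep-targeted resequencing, fits the anchor model, classifies the clonal
#' category, and estimates genetic distance, founder divisions and (for
#' pairs with cord blood) blood mixing.
#'
#' @param family a `twin_family`.
#' @param config a [model_config()].
#' @param seed integer seed for the targeted resequencing draw.
#' @return list with calls, targeted table, fit(s), and summary fields.
#' @export
analyse_family <- function(family, config = model_config(), seed = NULL) {
  calls <- classify_variants(family$table,
                             min_alt = family$params$detection_min_alt,
                             min_vaf = family$params$detection_min_vaf)
  cand <- as.character(calls$variant[calls$class %in% c("de_novo", "eem")])
  targeted <- if (length(cand))
    targeted_resequence(family, cand, seed = seed) else NULL
  inds <- family$individuals
  buccal <- paste0(inds, "_buccal")
  res <- list(family = family$family_id, calls = calls,
              targeted = targeted,
              zygosity_score = clonal_shared_fraction(family$table))
  if (family$zygosity == "DZ") {
    res$category <- "non_single_zygote"
    return(res)
  }
  if (length(inds) == 3) {                      # triplet
    vm <- vaf_matrix(targeted)[, buccal, drop = FALSE]
    colnames(vm) <- inds
    pairs <- utils::combn(inds, 2)
    fits <- list()
    for (i in seq_len(ncol(pairs))) {
      p <- pairs[, i]
      vp <- eem_vaf_pairs(targeted, calls, paste0(p, "_buccal"))
      fits[[paste(p, collapse = "-")]] <-
        tryCatch(fit_anchor_model(vp, config), error = function(e) NULL)
    }
    shared <- shared_clonal_counts(vm)
    ok <- !vapply(fits, is.null, logical(1))
    res$pairwise_fits <- fits
    res$topology <- if (all(ok))
      triplet_topology(fits, shared[names(fits)]) else
        list(newick = NA_character_, resolved = FALSE,
             reason = "pairwise fit failure")
    res$category <- "triplet"
    return(res)
  }
  vp <- eem_vaf_pairs(targeted, calls, buccal)
  fit <- tryCatch(fit_anchor_model(vp, config), error = function(e) e)
  if (inherits(fit, "error")) {
    res$category <- "failed"
    res$qc <- conditionMessage(fit)
    return(res)
  }
  res$fit <- fit
  res$category <- fit$category
  res$genetic_distance <- genetic_distance(calls)
  informative <- select_informative(targeted, calls, buccal)
  res$n_unique_clonal <- nrow(informative)
  res$divisions <- divisions_between_founders(nrow(informative),
                                              config$founder_rate)
  cords <- intersect(paste0(inds, "_cord_blood"), targeted$samples)
  if (length(cords) == 2)
    res$mixing <- estimate_mixing(informative, targeted, cords,
                                  family$params$seq_error)
  res
}

#' Run the full simulation-and-inference pipeline
#'
#' Simulates a cohort, analyses every family, runs the cohort-level
#' statistics (clonal category vs membrane type by Monte Carlo Fisher;
#' genetic distance vs membrane type by Kruskal-Wallis), and summarises
#' recovery against the simulation truth. Deterministic given `seed`; one
#' report row per simulated family regardless of per-family failures.
#'
#' @param config a [cohort_config()] or path to a YAML config.
#' @param seed integer master seed.
#' @param out_dir optional output directory; when given, writes
#'   `report.tsv`, `fits.json`, `stats.json` and `recovery.json`.
#' @param model a [model_config()].
#' @return list of class `cohort_report`: `report` (data.frame), `stats`,
#'   `recovery`, `analyses`, `cohort`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1,
                         out_dir = NULL, model = model_config()) {
  cohort <- simulate_cohort(config, seed)
  analyses <- lapply(seq_along(cohort$families), function(i)
    analyse_family(cohort$families[[i]], model,
                   seed = derive_seed(seed, 10000 + i)))
  names(analyses) <- names(cohort$families)
  rows <- lapply(names(analyses), function(f) {
    a <- analyses[[f]]
    tr <- cohort$truth[[f]]
    mix <- if (!is.null(a$mixing) && identical(a$mixing$status, "ok"))
      a$mixing$estimates else NULL
    data.frame(
      family = f, zygosity = tr$zygosity, membrane = tr$membrane,
      true_mode = tr$mode, category = a$category,
      a_hat = a$fit$a %||% NA_real_, b_hat = a$fit$b %||% NA_real_,
      anchor_absent = a$fit$anchor_absent %||% NA,
      genetic_distance = a$genetic_distance %||% NA_integer_,
      n_unique_clonal = a$n_unique_clonal %||% NA_integer_,
      divisions = a$divisions %||% NA_integer_,
      true_a = tr$true_a, true_b = tr$true_b, true_f = tr$f,
      m_hat_1 = if (!is.null(mix)) mix$m[1] else NA_real_,
      m_hat_2 = if (!is.null(mix) && nrow(mix) > 1) mix$m[2] else NA_real_,
      zygosity_score = a$zygosity_score %||% NA_real_,
      qc = a$qc %||% "", stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  # cohort statistics over MZ pairs with a fitted three-way category
  mz <- report[report$zygosity == "MZ" &
                 report$category %in% c("para", "sub", "full"), ]
  stats_out <- list()
  if (nrow(mz) && length(unique(mz$membrane)) >= 2) {
    tab <- table(factor(mz$membrane,
                        levels = intersect(c("MCMA", "MCDA", "DCDA"),
                                           unique(mz$membrane))),
                 factor(mz$category, levels = c("para", "sub", "full")))
    tab <- as.matrix(tab)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    ft <- tryCatch(fisher_montecarlo(tab, B = 10000,
                                     seed = derive_seed(seed, 77)),
                   error = function(e) NULL)
    stats_out$category_vs_membrane <-
      list(table = tab, p.value = ft$p.value %||% NA_real_)
    dist_groups <- split(mz$genetic_distance, mz$membrane)
    dist_groups <- dist_groups[lengths(dist_groups) > 0]
    if (length(dist_groups) >= 2) {
      kw <- kruskal_wallis_bonferroni(dist_groups, pairwise = TRUE)
      stats_out$distance_vs_membrane <-
        list(H = kw$statistic, p.value = kw$p.value,
             pairwise = kw$pairwise, groups = names(dist_groups))
    }
  }
  # recovery vs truth
  mzall <- report[report$zygosity == "MZ" & report$true_mode %in%
                    c("para", "sub", "full"), ]
  mono <- report[report$membrane %in% c("MCMA", "MCDA") &
                   !is.na(report$true_f), ]
  m_err <- c((1 - mono$m_hat_1) - mono$true_f,
             (1 - mono$m_hat_2) - mono$true_f)
  recovery <- list(
    n_families = nrow(report),
    category_accuracy = if (nrow(mzall))
      mean(mzall$category == mzall$true_mode) else NA_real_,
    ab_rmse = if (nrow(mzall))
      sqrt(mean(c(mzall$a_hat - mzall$true_a,
                  mzall$b_hat - mzall$true_b)^2, na.rm = TRUE))
      else NA_real_,
    mixing_rmse = if (length(m_err))
      sqrt(mean(m_err^2, na.rm = TRUE)) else NA_real_,
    dz_max_zygosity_score = if (any(report$zygosity == "DZ"))
      max(report$zygosity_score[report$zygosity == "DZ"], na.rm = TRUE)
      else NA_real_)
  out <- structure(list(report = report, stats = stats_out,
                        recovery = recovery, analyses = analyses,
                        cohort = cohort, seed = seed),
                   class = "cohort_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report, file.path(out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fits <- lapply(analyses, function(a) {
      if (is.null(a$fit)) return(list(category = a$category))
      list(a = a$fit$a, b = a$fit$b, category = a$fit$category,
           anchor_absent = a$fit$anchor_absent,
           anchor = a$fit$anchor$members,
           counter = a$fit$counter$members, epsilon = a$fit$epsilon)
    })
    jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    jsonlite::write_json(recovery, file.path(out_dir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort_report: %d families; category accuracy %.2f\n",
              nrow(x$report), x$recovery$category_accuracy))
  print(table(x$report$membrane, x$report$category))
  invisible(x)
}
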