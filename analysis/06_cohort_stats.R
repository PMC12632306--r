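# Cohort-level statistics: clonal category vs fetal-membrane type (Monte
# Carlo Fisher with fixed margins), genetic distance vs membrane type
# (tie-corrected Kruskal-Wallis with Bonferroni pairwise tests), and the
# statistics' own calibration checks.

source("analysis/00_config.R")

rep <- run_pipeline(cohort_config(), seed = ANALYSIS_SEED)
r <- rep$report
mz <- r[r$zygosity == "MZ" & r$category %in% c("para", "sub", "full"), ]

tab <- table(factor(mz$membrane, levels = c("MCMA", "MCDA", "DCDA")),
              factor(mz$category, levels = c("para", "sub", "full")))
tab <- as.matrix(tab)
print(tab)
ft <- fisher_montecarlo(tab[rowSums(tab) > 0, colSums(tab) > 0,
                            drop = FALSE],
                        B = 100000, seed = derive_seed(ANALYSIS_SEED, 31))
message(sprintf("category vs membrane: Monte Carlo Fisher P = %.4f (B = %d)",
                ft$p.value, ft$B))

groups <- split(mz$genetic_distance, mz$membrane)
groups <- groups[lengths(groups) > 0]
kw <- kruskal_wallis_bonferroni(groups, pairwise = TRUE)
message(sprintf("genetic distance vs membrane: H(%d) = %.2f, P = %.4f",
                kw$df, kw$statistic, kw$p.value))
print(kw$pairwise)

# amnionicity contrast: monoamniotic (MCMA) vs diamniotic (MCDA + DCDA)
amn <- table(mz$membrane == "MCMA", mz$category == "full")
f2 <- fisher_exact_2x2(as.matrix(amn))
message(sprintf("full-identical vs monoamnionicity: exact P = %.4f",
                f2$p.value))

stats_out <- list(
  category_table = tab,
  fisher_mc_p = ft$p.value,
  kw_H = kw$statistic, kw_p = kw$p.value, kw_pairwise = kw$pairwise,
  amnionicity_p = f2$p.value)
jsonlite::write_json(stats_out, file.path(RESULTS_DIR, "cohort_stats.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     force = TRUE)
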