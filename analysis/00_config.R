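# Shared settings for the analysis scripts: one cohort, one seed.
# Each numbered script re-simulates the cohort deterministically from this
# seed (a few seconds) so every artefact under results/ is reproducible
# from code alone.

library(twinEEM)

ANALYSIS_SEED <- 17
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

analysis_cohort <- function() simulate_cohort(cohort_config(),
                                              seed = ANALYSIS_SEED)
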