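# Simulate the study cohort: 8 MCMA + 7 MCDA + 7 DCDA monozygotic pairs,
# 1 DCTA monozygotic triplet and 6 dizygotic control pairs, each with
# trio-complete 60x whole-genome read counts over de novo variants, EEMs
# and inherited variants. Writes per-family variant tables (TSV and VCF)
# and the ground-truth record.

source("analysis/00_config.R")

coh <- analysis_cohort()
print(coh)

out <- file.path(RESULTS_DIR, "cohort")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (fam in coh$families) {
  write_variant_table(fam$table,
                      file.path(out, paste0(fam$family_id, ".tsv")), "tsv")
  write_variant_table(fam$table,
                      file.path(out, paste0(fam$family_id, ".vcf")), "vcf")
}
write.table(coh$metadata, file.path(out, "metadata.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(lapply(coh$truth, function(t)
  t[setdiff(names(t), "variant_class")]),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

n_eem <- vapply(coh$families, function(f)
  sum(f$truth$variant_class == "eem"), double(1))
message(sprintf("wrote %d families (median %d somatic EEM sites each) to %s",
                length(coh$families), round(median(n_eem)), out))
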