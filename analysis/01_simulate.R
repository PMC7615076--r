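#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — two discovery cohorts (clinical
# and pre-clinical style, 10/10/10 each, seven lectin pulldowns) and one
# validation cohort (39/28/28, three lectins, with a 25-sample
# instrument-failure batch on AAL) — and write every input table to disk.

source("analysis/00_config.R")
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

cohorts <- list(D1 = discovery_config("D1", seed = 101L),
                D2 = discovery_config("D2", seed = 102L))
val_cfg <- validation_config(seed = 103L)

for (nm in names(cohorts)) {
  sim <- simulate_cohort(cohorts[[nm]])
  write_sample_metadata(sim$metadata,
                        file.path(DATA_DIR, paste0("metadata_", nm, ".csv")))
  for (l in names(sim$dda))
    write_dda_table(sim$dda[[l]],
                    file.path(DATA_DIR, sprintf("dda_%s_%s.tsv", nm, l)))
  cat(sprintf("cohort %s: %d samples, %d lectin DDA tables\n",
              nm, nrow(sim$metadata), length(sim$dda)))
}

val <- simulate_cohort(val_cfg)
write_sample_metadata(val$metadata,
                      file.path(DATA_DIR, "metadata_VAL.csv"))
for (l in names(val$mrm))
  write_transition_report(val$mrm[[l]],
                          file.path(DATA_DIR,
                                    sprintf("mrm_VAL_%s.csv", l)))
cat(sprintf("validation: %d samples, %d lectin MRM reports\n",
            nrow(val$metadata), length(val$mrm)))

jsonlite::write_json(
  list(planted_effects = val_cfg$effect_table,
       outlier_batch = val_cfg$outlier_batch,
       seeds = list(D1 = 101L, D2 = 102L, VAL = 103L)),
  file.path(DATA_DIR, "truth.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("truth registry written to", file.path(DATA_DIR, "truth.json"), "\n")
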