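#!/usr/bin/env Rscript
# Stage 5: multi-marker panels. For each lectin and for the combined
# feature space: L1-penalized logistic models over lectin-qualified
# peptides, leave-one-out cross-validation with per-fold inner penalty
# selection, pooled-prediction AUC / sensitivity / specificity with
# stratified bootstrap intervals, and selection-frequency stability with
# the >= 50% stable peptide set.

source("analysis/00_config.R")
out_dir <- "results/panel"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
cfg <- ANALYSIS_CONFIG

meta <- read_sample_metadata(file.path(DATA_DIR, "metadata_VAL.csv"))
flags <- utils::read.delim("results/mrm_qc/sample_flags.tsv")
# outlier removal is per lectin: an instrument failure on one pulldown
# does not invalidate the same serum's other pulldowns; the combined
# model drops the union
outliers_of <- function(scope) {
  if (identical(scope, "combined"))
    unique(flags$sample[flags$flagged])
  else unique(flags$sample[flags$flagged & flags$lectin == scope])
}

mats <- lapply(VALIDATION_LECTINS, function(l) {
  tt <- read_transition_report(file.path(DATA_DIR,
                                         sprintf("mrm_VAL_%s.csv", l)),
                               lectin = l, standards = STANDARDS)
  aggregate_transitions(tt)
})
names(mats) <- VALIDATION_LECTINS

scopes <- c(VALIDATION_LECTINS, "combined")
metrics <- list(); stability <- list()
for (sc in scopes) {
  d <- build_design(mats, meta, sc, exclude_samples = outliers_of(sc))
  panel <- loocv_panel(d$X, d$y, cfg)
  m <- panel$metrics
  my <- panel$metrics_youden
  cat(sprintf(
    "%-8s n=%3d  AUC=%5.1f%% (%.1f%%, %.1f%%)  at 0.5: Sens=%5.1f%% Spec=%5.1f%%  at Youden %.3f: Sens=%5.1f%% Spec=%5.1f%%  stable peptides: %d\n",
    sc, panel$n, 100 * m$value[1], 100 * m$lower[1], 100 * m$upper[1],
    100 * m$value[2], 100 * m$value[3], panel$threshold_youden,
    100 * my$value[2], 100 * my$value[3], length(panel$stable)))
  if (length(panel$stable))
    cat("   stable:", paste(utils::head(panel$stable, 8), collapse = ", "),
        if (length(panel$stable) > 8) "..." else "", "\n")
  m$threshold <- "fixed_0.5"
  my$threshold <- "youden"
  my$lower <- NA_real_; my$upper <- NA_real_
  m <- rbind(m, my[names(m)])
  m$scope <- sc; m$n <- panel$n
  m$value <- round(m$value, 4)
  m$lower <- round(m$lower, 4); m$upper <- round(m$upper, 4)
  metrics[[sc]] <- m[c("scope", "n", "threshold", "metric", "value",
                       "lower", "upper")]
  s <- panel$stability
  s$scope <- sc
  s$stable <- s$fraction >= cfg$stability_frac
  s$fraction <- round(s$fraction, 4)
  stability[[sc]] <- s[c("scope", "feature", "count", "fraction",
                         "stable")]
}

write_results(list(panel_metrics = do.call(rbind, metrics),
                   panel_stability = do.call(rbind, stability)),
              out_dir, cfg)
cat("panel tables written under", out_dir, "\n")
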