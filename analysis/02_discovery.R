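#!/usr/bin/env Rscript
# Stage 2: DDA discovery. Per cohort and lectin: evidence filtering,
# peptide-to-protein summing, log2, missingness-routed imputation,
# pooled-t differential testing; then strict and expanded shortlists,
# cross-cohort concordance, the overlap-aware candidate summary, and
# the lectin ranking that selects the validation assay.

source("analysis/00_config.R")
out_dir <- "results/discovery"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
cfg <- ANALYSIS_CONFIG

res <- do.call(rbind, lapply(c("D1", "D2"), function(nm) {
  meta <- read_sample_metadata(file.path(DATA_DIR,
                                         paste0("metadata_", nm, ".csv")))
  do.call(rbind, lapply(DISCOVERY_LECTINS, function(l) {
    dda <- read_dda_table(file.path(DATA_DIR,
                                    sprintf("dda_%s_%s.tsv", nm, l)),
                          "peptides", lectin = l, cohort = nm)
    discover_dda(dda, meta, cfg)
  }))
}))
cat(sprintf("tested %d features per comparison across %d lectins x 2 cohorts\n",
            nrow(res) / 4 / length(DISCOVERY_LECTINS),
            length(DISCOVERY_LECTINS)))

strict <- shortlist_candidates(res, "strict", cfg)
expanded <- shortlist_candidates(res, "expanded", cfg)
cat(sprintf("strict shortlist (p < %.2f, |log2FC| > %.1f): %d entries\n",
            cfg$p_discovery, cfg$fc_discovery_log2, nrow(strict)))
cat(sprintf("expanded shortlist (p < %.1f, no fold-change filter): %d entries\n",
            cfg$p_expanded, nrow(expanded)))

concordant <- do.call(rbind, lapply(DISCOVERY_LECTINS, function(l) {
  a <- res[res$lectin == l & res$cohort == "D1", ]
  b <- res[res$lectin == l & res$cohort == "D2", ]
  cc <- cross_cohort_overlap(a, b, cfg$concordance_fc_log2)
  if (nrow(cc)) cbind(lectin = l, cc) else NULL
}))
cat(sprintf("cross-cohort concordant at |log2FC| > %.1f: %d features\n",
            cfg$concordance_fc_log2, NROW(concordant)))

cand <- data.frame(lectin = strict$lectin, cohort = strict$cohort,
                   comparison = strict$comparison,
                   protein = strict$feature, stringsAsFactors = FALSE)
summ <- summarize_candidates(cand)
ranking <- rank_lectins(cand, n = 3L)
cat("distinct candidate proteins per lectin (overlap-aware):\n")
print(summ$lectin_totals)
cat("lectins carried to validation:", paste(ranking, collapse = ", "),
    "\n")

res$log2fc <- round(res$log2fc, 6); res$p <- signif(res$p, 6)
write_results(list(
  differential = res,
  shortlist_strict = strict,
  shortlist_expanded = expanded,
  cross_cohort_concordant = concordant,
  candidate_cells = summ$cells,
  candidate_lectin_totals = data.frame(
    lectin = names(summ$lectin_totals),
    total_distinct = as.integer(summ$lectin_totals)),
  lectin_ranking = data.frame(rank = seq_along(ranking),
                              lectin = as.character(ranking))),
  out_dir, cfg)
cat("discovery tables written under", out_dir, "\n")
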