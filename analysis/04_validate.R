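#!/usr/bin/env Rscript
# Stage 4: peptide-level validation. Pooled t per peptide and
# comparison with BH adjustment within each (lectin, comparison)
# family, then the protein-level consistency rule: a protein validates
# when at least one peptide is significant (q < 0.05, |log2FC| > 0.5 in
# either comparison) and all of its measured peptides agree in
# direction.

source("analysis/00_config.R")
out_dir <- "results/validation"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
cfg <- ANALYSIS_CONFIG

meta <- read_sample_metadata(file.path(DATA_DIR, "metadata_VAL.csv"))
flags <- utils::read.delim("results/mrm_qc/sample_flags.tsv")

res <- do.call(rbind, lapply(VALIDATION_LECTINS, function(l) {
  tt <- read_transition_report(file.path(DATA_DIR,
                                         sprintf("mrm_VAL_%s.csv", l)),
                               lectin = l, standards = STANDARDS)
  m <- aggregate_transitions(tt)
  # each lectin's analysis is independent: drop only the samples whose
  # runs failed QC on this lectin
  bad <- flags$sample[flags$flagged & flags$lectin == l]
  keep <- setdiff(colnames(m), bad)
  sub <- m[, keep, drop = FALSE]
  for (a in c("protein_map", "standards", "lectin"))
    attr(sub, a) <- attr(m, a)
  peptide_differential(sub, meta$group[match(keep, meta$sample_id)])
}))
cat(sprintf("tested %d peptide x comparison records across %d lectins\n",
            nrow(res), length(VALIDATION_LECTINS)))

for (mode in c("direction", "strict")) {
  s <- consistency_filter(res, mode, cfg)
  cat(sprintf("[%s rule]\n", mode))
  for (i in seq_len(nrow(s)))
    cat(sprintf(
      "  %-4s %d significant peptides; %d proteins any-significant; %d consistent (%.1f%%); up: %s; down: %s\n",
      s$lectin[i], s$n_significant_peptides[i],
      s$n_any_significant_proteins[i], s$n_consistent_proteins[i],
      s$pct_consistent[i], s$up[i], s$down[i]))
  assign(paste0("summary_", mode), s)
}

# re-examine validated proteins in the discovery-stage data
validated <- do.call(rbind, lapply(seq_len(nrow(summary_direction)),
                                   function(i) {
  s <- summary_direction[i, ]
  up <- strsplit(s$up, ",")[[1]]; down <- strsplit(s$down, ",")[[1]]
  if (!length(c(up, down))) return(NULL)
  data.frame(lectin = s$lectin, protein = c(up, down),
             direction = rep(c("up", "down"), c(length(up), length(down))),
             stringsAsFactors = FALSE)
}))
disc <- utils::read.delim("results/discovery/differential.tsv")
crosscheck <- crosscheck_in_discovery(validated,
                                      disc[disc$cohort == "D2", ])
cat(sprintf("crosscheck in pre-clinical discovery data: %d/%d detected\n",
            sum(crosscheck$detected), nrow(crosscheck)))

res$log2fc <- round(res$log2fc, 6)
res$p <- signif(res$p, 6); res$q <- signif(res$q, 6)
crosscheck$log2fc <- round(crosscheck$log2fc, 6)
crosscheck$p <- signif(crosscheck$p, 6)
write_results(list(
  peptide_differential = res,
  consistency_direction = summary_direction,
  consistency_strict = summary_strict,
  validated_proteins = validated,
  discovery_crosscheck = crosscheck),
  out_dir, cfg)
cat("validation tables written under", out_dir, "\n")
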