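#!/usr/bin/env Rscript
# Stage 3: MRM quality control. Sums transitions to peptide quantities,
# computes the linear-scale %CV of the ovalbumin and SIS standard
# peptides against the 10% limit, and flags outlier samples by robust z
# on standard levels. Flags are advisory; the retained-sample list is
# written for the validation and panel stages.

source("analysis/00_config.R")
out_dir <- "results/mrm_qc"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
cfg <- ANALYSIS_CONFIG

std_tab <- list(); flag_tab <- list()
for (l in VALIDATION_LECTINS) {
  tt <- read_transition_report(file.path(DATA_DIR,
                                         sprintf("mrm_VAL_%s.csv", l)),
                               lectin = l, standards = STANDARDS)
  q <- qc_report(tt, cfg)
  q$standards$lectin <- l
  q$samples$lectin <- l
  std_tab[[l]] <- q$standards
  flag_tab[[l]] <- q$samples
  n_flag <- sum(q$samples$flagged)
  cat(sprintf("%-4s standards %%CV: %s | %d sample(s) flagged\n", l,
              paste(sprintf("%.1f", q$standards$cv_pct), collapse = ", "),
              n_flag))
}
std_tab <- do.call(rbind, std_tab)
flag_tab <- do.call(rbind, flag_tab)

# recompute %CV after dropping flagged samples: the QC pass statement
# applies to the retained set
outliers <- unique(flag_tab$sample[flag_tab$flagged])
cat(sprintf("outlier samples removed before downstream stages: %d\n",
            length(outliers)))
post <- do.call(rbind, lapply(VALIDATION_LECTINS, function(l) {
  tt <- read_transition_report(file.path(DATA_DIR,
                                         sprintf("mrm_VAL_%s.csv", l)),
                               lectin = l, standards = STANDARDS)
  retained <- setdiff(unique(tt$sample), outliers)
  s <- qc_report(tt, cfg, retain = retained)$standards
  s$lectin <- l
  s
}))
cat(sprintf("all standards < %.0f%% CV after outlier removal: %s\n",
            cfg$cv_limit_pct, all(post$pass)))

std_tab$cv_pct <- round(std_tab$cv_pct, 3)
post$cv_pct <- round(post$cv_pct, 3)
flag_tab$score <- round(flag_tab$score, 4)
flag_tab$standard_level <- round(flag_tab$standard_level, 4)
write_results(list(
  standards_cv = std_tab[c("lectin", "peptide", "role", "cv_pct", "pass")],
  standards_cv_after_removal = post[c("lectin", "peptide", "role",
                                      "cv_pct", "pass")],
  sample_flags = flag_tab[c("lectin", "sample", "standard_level", "score",
                            "flagged")],
  retained_samples = data.frame(sample = setdiff(unique(flag_tab$sample),
                                                 outliers))),
  out_dir, cfg)
cat("QC tables written under", out_dir, "\n")
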