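# Shared configuration for the analysis workflow. Sourced by the
# numbered scripts; everything downstream of 01_simulate.R reads its
# inputs back from disk, so each stage can be rerun independently.

library(glycomark)

DATA_DIR <- "results/simdata"
DISCOVERY_LECTINS <- c("AAL", "CON-A", "ECA", "L-PHA", "SNA", "STL", "WFA")
VALIDATION_LECTINS <- c("AAL", "SNA", "STL")

# planted truth: a handful of lectin-protein glycoforms that genuinely
# differ between cases and controls, concentrated on the lectins the
# validation assay will carry forward
planted_effects <- function(lectins) {
  et <- data.frame(
    lectin = c("AAL", "AAL", "AAL", "SNA", "SNA", "STL", "STL", "STL",
               "ECA", "WFA"),
    protein = c("PROT001", "PROT002", "PROT003", "PROT004", "PROT005",
                "PROT006", "PROT007", "PROT001", "PROT008", "PROT009"),
    comparison = c("case-vs-benign", "case-vs-healthy", "case-vs-benign",
                   "case-vs-benign", "case-vs-healthy", "case-vs-benign",
                   "case-vs-healthy", "case-vs-healthy", "case-vs-benign",
                   "case-vs-healthy"),
    effect = c(2.0, 1.8, -1.5, 1.6, -1.8, 2.2, 1.5, 1.4, 1.7, -1.6),
    stringsAsFactors = FALSE)
  et[et$lectin %in% lectins, , drop = FALSE]
}

discovery_config <- function(cohort, seed) {
  simulation_config(
    n_case = 10L, n_benign = 10L, n_healthy = 10L,
    lectins = DISCOVERY_LECTINS, n_proteins = 120L,
    peptides_per_protein = c(2L, 6L),
    effect_table = planted_effects(DISCOVERY_LECTINS),
    cohort = cohort, seed = seed)
}

validation_config <- function(seed) {
  simulation_config(
    n_case = 39L, n_benign = 28L, n_healthy = 28L,
    lectins = VALIDATION_LECTINS, n_proteins = 20L,
    peptides_per_protein = c(3L, 5L),
    effect_table = planted_effects(VALIDATION_LECTINS),
    outlier_batch = list(lectin = "AAL",
                         samples = sprintf("S%03d", 1:25),
                         shift_log2 = -1, inflation = 4),
    cohort = "VAL", seed = seed)
}

ANALYSIS_CONFIG <- analysis_config(seed = 20260925L, n_boot = 2000L)

# the simulator's internal-standard registry, needed to re-annotate
# transition tables read back from disk
STANDARDS <- list(
  ovalbumin = c("GGLEPINFQTAADQAR", "ISQAVHAAHAEINEAGR", "YPILPEYLQCVK"),
  sis = c("VTSIQDWVQK", "NLAVSQVVHK", "LSPIYNLVPVK"))
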