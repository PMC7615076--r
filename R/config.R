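#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' Defaults follow the study design the pipeline implements: discovery
#' shortlisting at unadjusted p < 0.05 with |log2 fold change| > 1 (strict)
#' or p < 0.1 with no fold-change filter (expanded); cross-cohort
#' concordance at |log2FC| > 0.5; validation significance at BH q < 0.05
#' and |log2FC| > 0.5; a 25% missingness boundary routing imputation;
#' protein-group filters of >= 2 peptides and score >= 5; a 10% ceiling on
#' internal-standard %CV; and a 50% selection-frequency cut for stable
#' panel peptides.
#'
#' @param p_discovery unadjusted p threshold for strict discovery
#'   shortlisting.
#' @param fc_discovery_log2 absolute log2 fold-change threshold paired with
#'   \code{p_discovery}.
#' @param p_expanded relaxed p threshold used when fold-change filtering is
#'   dropped.
#' @param concordance_fc_log2 absolute log2FC needed in both cohorts for a
#'   cross-cohort concordant candidate.
#' @param q_validation BH-adjusted q threshold at the validation stage.
#' @param fc_validation_log2 absolute log2FC threshold at the validation
#'   stage.
#' @param missing_frac_boundary fraction of missing samples at or above
#'   which a feature is imputed by minimum-value draws rather than local
#'   least squares.
#' @param min_peptides minimum peptide evidence for a protein group.
#' @param min_score minimum identification score for a protein group.
#' @param cv_limit_pct maximum acceptable internal-standard coefficient of
#'   variation, in percent.
#' @param stability_frac minimum selection fraction across cross-validation
#'   fits for a peptide to be called stable.
#' @param lls_k neighbour count for local least squares imputation.
#' @param outlier_robust_z robust z-score threshold for flagging outlier
#'   samples from internal standards.
#' @param classification_threshold predicted-probability cut for
#'   sensitivity/specificity.
#' @param minvalue_sd optional scalar override for the SD of minimum-value
#'   imputation draws; \code{NULL} estimates it from fully observed rows.
#' @param n_boot bootstrap replicates for panel metric intervals.
#' @param seed integer run seed.
#' @return a list of class \code{glyco_config}.
#' @export
analysis_config <- function(p_discovery = 0.05,
                            fc_discovery_log2 = 1.0,
                            p_expanded = 0.1,
                            concordance_fc_log2 = 0.5,
                            q_validation = 0.05,
                            fc_validation_log2 = 0.5,
                            missing_frac_boundary = 0.25,
                            min_peptides = 2L,
                            min_score = 5.0,
                            cv_limit_pct = 10.0,
                            stability_frac = 0.5,
                            lls_k = 10L,
                            outlier_robust_z = 3.5,
                            classification_threshold = 0.5,
                            minvalue_sd = NULL,
                            n_boot = 2000L,
                            seed = 1L) {
  cfg <- list(p_discovery = p_discovery,
              fc_discovery_log2 = fc_discovery_log2,
              p_expanded = p_expanded,
              concordance_fc_log2 = concordance_fc_log2,
              q_validation = q_validation,
              fc_validation_log2 = fc_validation_log2,
              missing_frac_boundary = missing_frac_boundary,
              min_peptides = as.integer(min_peptides),
              min_score = min_score,
              cv_limit_pct = cv_limit_pct,
              stability_frac = stability_frac,
              lls_k = as.integer(lls_k),
              outlier_robust_z = outlier_robust_z,
              classification_threshold = classification_threshold,
              minvalue_sd = minvalue_sd,
              n_boot = as.integer(n_boot),
              seed = as.integer(seed))
  for (nm in c("p_discovery", "p_expanded", "q_validation",
               "missing_frac_boundary", "stability_frac",
               "classification_threshold")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      stop(sprintf("'%s' must be a probability in (0, 1)", nm))
  }
  for (nm in c("fc_discovery_log2", "concordance_fc_log2",
               "fc_validation_log2")) {
    if (cfg[[nm]] < 0) stop(sprintf("'%s' must be >= 0", nm))
  }
  if (cfg$lls_k < 1L) stop("'lls_k' must be >= 1")
  if (cfg$cv_limit_pct <= 0) stop("'cv_limit_pct' must be > 0")
  if (!is.null(cfg$minvalue_sd) && cfg$minvalue_sd <= 0)
    stop("'minvalue_sd' must be > 0 when supplied")
  class(cfg) <- "glyco_config"
  cfg
}

#' Read/write an analysis configuration as YAML
#'
#' @param path file path.
#' @return \code{read_config} returns a \code{glyco_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param config a \code{glyco_config}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "glyco_config"))
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, TRUE)], path)
  invisible(path)
}
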