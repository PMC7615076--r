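#' Run the discovery stage on one DDA table
#'
#' Applies the canonical order of operations: evidence filtering,
#' peptide-to-protein summing, log2 transform, missingness-routed
#' imputation, then per-comparison differential testing. Internal
#' standard peptides are excluded from the feature set before testing.
#'
#' @param dda a linear-scale peptide-level DDA table (with a
#'   \code{protein} column).
#' @param metadata sample annotation.
#' @param config an \code{\link{analysis_config}}.
#' @param variant t-test variant passed to
#'   \code{\link{differential_test}}.
#' @return data.frame of differential results for both comparisons with
#'   lectin/cohort columns; attribute \code{routes} records imputation
#'   routing.
#' @export
discover_dda <- function(dda, metadata, config = analysis_config(),
                         variant = "student") {
  filtered <- filter_protein_groups(dda, config)
  prot <- sum_peptides_to_protein(filtered)
  lg <- log2_transform(prot)
  imp <- impute_matrix(lg, config)
  samples <- attr(imp, "samples")
  m <- as.matrix(imp[samples])
  rownames(m) <- imp$id
  std <- c("OVAL", "SIS")
  m <- m[setdiff(rownames(m), std), , drop = FALSE]
  groups <- metadata$group[match(samples, metadata$sample_id)]
  res <- do.call(rbind, lapply(c("case-vs-benign", "case-vs-healthy"),
                               function(cmp)
                                 differential_test(m, groups, cmp,
                                                   variant = variant)))
  res$lectin <- attr(dda, "lectin") %||% NA_character_
  res$cohort <- attr(dda, "cohort") %||% NA_character_
  rownames(res) <- NULL
  attr(res, "routes") <- attr(imp, "routes")
  res
}

#' Run the full synthetic pipeline end to end
#'
#' Simulates a discovery and a validation cohort, runs DDA discovery
#' (filter, impute, test, shortlist, summarize), MRM QC with outlier
#' flagging, peptide-level validation with the consistency rule, and the
#' LOOCV lasso panel on the validation data, writing every stage table
#' under \code{out_dir}. Deterministic for a fixed pair of
#' configurations: identical reruns produce identical files.
#'
#' @param sim_discovery a \code{\link{simulation_config}} for the
#'   discovery cohort, or a list of them (one per discovery cohort; with
#'   two cohorts a cross-cohort concordance table is also produced).
#' @param sim_validation a \code{\link{simulation_config}} for the
#'   validation cohort (its lectins are the panel/validation scope).
#' @param config an \code{\link{analysis_config}}.
#' @param out_dir output directory for result files.
#' @param panel_scopes lectin scopes for panel models; defaults to each
#'   validation lectin plus \code{"combined"}.
#' @return invisible list with the main in-memory results (discovery
#'   results, candidate summary, qc, validation summary, panels).
#' @export
run_pipeline <- function(sim_discovery, sim_validation,
                         config = analysis_config(), out_dir,
                         panel_scopes = NULL) {
  if (inherits(sim_discovery, "glyco_simconfig"))
    sim_discovery <- list(sim_discovery)
  discs <- lapply(sim_discovery, simulate_cohort)
  val <- simulate_cohort(sim_validation)

  # --- discovery stage -----------------------------------------------
  disc_res <- do.call(rbind, lapply(discs, function(disc)
    do.call(rbind, lapply(names(disc$dda), function(l)
      discover_dda(disc$dda[[l]], disc$metadata, config)))))
  rownames(disc_res) <- NULL
  strict <- shortlist_candidates(disc_res, "strict", config)
  expanded <- shortlist_candidates(disc_res, "expanded", config)
  cand <- data.frame(lectin = strict$lectin, cohort = strict$cohort,
                     comparison = strict$comparison,
                     protein = strict$feature, stringsAsFactors = FALSE)
  summ <- summarize_candidates(cand)
  ranking <- rank_lectins(cand, n = min(3L, length(unique(cand$lectin))))
  cohorts <- unique(disc_res$cohort)
  concordant <- NULL
  if (length(cohorts) == 2L) {
    concordant <- do.call(rbind, lapply(unique(disc_res$lectin),
                                        function(l) {
      a <- disc_res[disc_res$lectin == l & disc_res$cohort == cohorts[1], ]
      b <- disc_res[disc_res$lectin == l & disc_res$cohort == cohorts[2], ]
      cc <- cross_cohort_overlap(a, b, config$concordance_fc_log2)
      if (nrow(cc)) cbind(lectin = l, cc) else NULL
    }))
  }

  # --- MRM QC + validation stage -------------------------------------
  qc <- lapply(val$mrm, qc_report, config = config)
  outliers <- unlist(lapply(qc, function(q)
    q$samples$sample[q$samples$flagged]), use.names = FALSE)
  mats <- lapply(val$mrm, aggregate_transitions)
  keep_samples <- setdiff(val$metadata$sample_id, outliers)
  groups_of <- function(s) val$metadata$group[match(s,
                                                    val$metadata$sample_id)]
  val_res <- do.call(rbind, lapply(mats, function(m) {
    sub <- m[, intersect(colnames(m), keep_samples), drop = FALSE]
    for (a in c("protein_map", "standards", "lectin"))
      attr(sub, a) <- attr(m, a)
    peptide_differential(sub, groups_of(colnames(sub)))
  }))
  rownames(val_res) <- NULL
  consistency <- consistency_filter(val_res, "direction", config)

  # --- panel stage ----------------------------------------------------
  scopes <- panel_scopes %||% c(names(mats), "combined")
  panels <- lapply(scopes, function(sc) {
    d <- build_design(mats, val$metadata, sc, exclude_samples = outliers)
    loocv_panel(d$X, d$y, config)
  })
  names(panels) <- scopes
  panel_tab <- do.call(rbind, lapply(scopes, function(sc) {
    p <- panels[[sc]]
    data.frame(scope = sc, n = p$n,
               metric = p$metrics$metric,
               value = round(p$metrics$value, 4),
               lower = round(p$metrics$lower, 4),
               upper = round(p$metrics$upper, 4),
               stringsAsFactors = FALSE)
  }))
  stab_tab <- do.call(rbind, lapply(scopes, function(sc) {
    s <- panels[[sc]]$stability
    s$scope <- sc
    s$stable <- s$fraction >= config$stability_frac
    s[c("scope", "feature", "count", "fraction", "stable")]
  }))

  qc_tab <- do.call(rbind, lapply(names(qc), function(l) {
    s <- qc[[l]]$standards
    s$lectin <- l
    s[c("lectin", "peptide", "role", "cv_pct", "pass")]
  }))
  qc_tab$cv_pct <- round(qc_tab$cv_pct, 3)
  flag_tab <- do.call(rbind, lapply(names(qc), function(l) {
    s <- qc[[l]]$samples
    s$lectin <- l
    s$score <- round(s$score, 4)
    s$standard_level <- round(s$standard_level, 4)
    s[c("lectin", "sample", "standard_level", "score", "flagged")]
  }))

  disc_out <- disc_res
  disc_out$log2fc <- round(disc_out$log2fc, 6)
  disc_out$p <- signif(disc_out$p, 6)
  val_out <- val_res
  val_out$log2fc <- round(val_out$log2fc, 6)
  val_out$p <- signif(val_out$p, 6)
  val_out$q <- signif(val_out$q, 6)

  results <- list(
    discovery_differential = disc_out,
    discovery_candidates = cand,
    candidate_cells = summ$cells,
    candidate_lectin_totals = data.frame(
      lectin = names(summ$lectin_totals),
      total_distinct = as.integer(summ$lectin_totals)),
    lectin_ranking = data.frame(rank = seq_along(ranking),
                                lectin = as.character(ranking)),
    qc_standards = qc_tab,
    qc_sample_flags = flag_tab,
    validation_differential = val_out,
    validation_consistency = consistency,
    panel_metrics = panel_tab,
    panel_stability = stab_tab)
  if (!is.null(concordant)) {
    concordant$log2fc_a <- round(concordant$log2fc_a, 6)
    concordant$log2fc_b <- round(concordant$log2fc_b, 6)
    concordant$p_a <- signif(concordant$p_a, 6)
    concordant$p_b <- signif(concordant$p_b, 6)
    results$cross_cohort_concordant <- concordant
  }
  write_results(results, out_dir, config)

  invisible(list(discovery = disc_res, strict = strict,
                 expanded = expanded, summary = summ, ranking = ranking,
                 concordant = concordant, qc = qc, outliers = outliers,
                 validation = val_res, consistency = consistency,
                 panels = panels))
}
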