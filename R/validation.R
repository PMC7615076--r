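#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the inputs and applies the BH step-up procedure: sort p
#' ascending, take running minima of p(j) * m / j from the largest rank
#' down, cap at 1, and map back to input order.
#'
#' @param p p values in (0, 1].
#' @return q values, same order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (anyNA(p) || any(p <= 0 | p > 1))
    stop("p values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Peptide-level differential testing with BH FDR
#'
#' Pooled-variance two-sided t per peptide for each case-control
#' comparison, with BH adjustment within each (lectin, comparison)
#' family — each lectin's assay is analysed independently. Standard
#' peptides are excluded.
#'
#' @param m peptide matrix (log2) from
#'   \code{\link{aggregate_transitions}}.
#' @param groups group labels aligned with the matrix columns.
#' @param comparisons comparisons to run.
#' @return data.frame (feature, protein, lectin, comparison, log2fc, p,
#'   q, direction).
#' @export
peptide_differential <- function(m, groups,
                                 comparisons = c("case-vs-benign",
                                                 "case-vs-healthy")) {
  std <- unlist(attr(m, "standards"), use.names = FALSE)
  keep <- setdiff(rownames(m), std)
  sub <- m[keep, , drop = FALSE]
  pm <- attr(m, "protein_map")
  out <- do.call(rbind, lapply(comparisons, function(cmp) {
    res <- differential_test(sub, groups, cmp, variant = "student")
    res$q <- bh_adjust(res$p)
    res
  }))
  out$protein <- if (is.null(pm)) NA_character_ else unname(pm[out$feature])
  out$lectin <- attr(m, "lectin") %||% NA_character_
  rownames(out) <- NULL
  out[c("feature", "protein", "lectin", "comparison", "log2fc", "p", "q",
        "direction")]
}

#' Consistency percentage, as reported in validation summaries
#'
#' @param n_consistent proteins with all measured peptides consistent.
#' @param n_any proteins with at least one significant peptide.
#' @return percentage rounded to one decimal.
#' @export
consistency_percentage <- function(n_consistent, n_any) {
  if (n_any <= 0) stop("'n_any' must be positive")
  round(100 * n_consistent / n_any, 1)
}

#' Protein-level consistency filter over peptide differential results
#'
#' A peptide is significant when, in either comparison, q falls below
#' \code{q_validation} and |log2FC| exceeds \code{fc_validation_log2}. A
#' protein enters the any-significant count when at least one of its
#' peptides is significant. Under \code{mode = "direction"} (default) a
#' protein is consistent when, additionally, all of its measured
#' peptides share one fold-change sign (each peptide's direction taken
#' from its larger-|log2FC| comparison); under \code{mode = "strict"}
#' every measured peptide must itself be significant and share the sign.
#'
#' @param results output of \code{\link{peptide_differential}} covering
#'   both comparisons (optionally several lectins).
#' @param mode \code{"direction"} or \code{"strict"}.
#' @param config an \code{\link{analysis_config}}.
#' @return data.frame, one row per lectin: n_significant_peptides,
#'   n_any_significant_proteins, n_consistent_proteins, pct_consistent,
#'   up (comma-separated), down. Attribute \code{proteins} holds the
#'   per-protein evidence table.
#' @export
consistency_filter <- function(results, mode = c("direction", "strict"),
                               config = analysis_config()) {
  mode <- match.arg(mode)
  if (anyNA(results$protein))
    stop("unmapped peptide(s) in results")
  results$lectin[is.na(results$lectin)] <- "(all)"
  per_lectin <- lapply(split(results, results$lectin), function(res) {
    sig_row <- !is.na(res$q) & res$q < config$q_validation &
      abs(res$log2fc) > config$fc_validation_log2
    # per-peptide: significance in either comparison; direction from the
    # comparison with the larger |log2fc|
    peps <- split(seq_len(nrow(res)), res$feature)
    pep_tab <- data.frame(
      feature = names(peps),
      protein = vapply(peps, function(i) res$protein[i[1]], ""),
      significant = vapply(peps, function(i) any(sig_row[i]), TRUE),
      direction = vapply(peps, function(i) {
        j <- i[which.max(abs(res$log2fc[i]))]
        res$direction[j]
      }, ""),
      disagreeing = vapply(peps, function(i)
        length(unique(res$direction[i][res$direction[i] != "flat"])) > 1L,
        TRUE),
      stringsAsFactors = FALSE)
    prot <- split(pep_tab, pep_tab$protein)
    any_sig <- vapply(prot, function(pt) any(pt$significant), TRUE)
    consistent <- vapply(prot, function(pt) {
      dirs <- unique(pt$direction)
      same <- length(dirs) == 1L && dirs != "flat"
      if (mode == "strict") same && all(pt$significant)
      else same && any(pt$significant)
    }, TRUE)
    dir_of <- vapply(prot, function(pt) pt$direction[1], "")
    up <- sort(names(prot)[consistent & dir_of == "up"])
    down <- sort(names(prot)[consistent & dir_of == "down"])
    n_any <- sum(any_sig); n_cons <- sum(consistent)
    data.frame(
      lectin = res$lectin[1],
      n_significant_peptides = sum(pep_tab$significant),
      n_any_significant_proteins = n_any,
      n_consistent_proteins = n_cons,
      pct_consistent = if (n_any > 0)
        consistency_percentage(n_cons, n_any) else NA_real_,
      up = paste(up, collapse = ","),
      down = paste(down, collapse = ","),
      stringsAsFactors = FALSE) -> row
    attr(row, "peptides") <- pep_tab
    row
  })
  out <- do.call(rbind, per_lectin)
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  attr(out, "proteins") <- lapply(per_lectin, attr, "peptides")
  out
}

#' Cross-check validated proteins in discovery-stage results
#'
#' Joins each validated (lectin, protein) against a discovery-stage
#' differential result list and reports the discovery log2 fold change,
#' p value, and whether the direction agrees; proteins absent from the
#' discovery data are reported as not detected.
#'
#' @param validated data.frame with columns lectin, protein, direction.
#' @param discovery data.frame with columns lectin, feature (protein
#'   id), comparison, log2fc, p.
#' @return data.frame, one row per validated (lectin, protein,
#'   discovery comparison), with detected/concordant flags.
#' @export
crosscheck_in_discovery <- function(validated, discovery) {
  stopifnot(all(c("lectin", "protein", "direction") %in% names(validated)),
            all(c("lectin", "feature", "comparison", "log2fc", "p") %in%
                  names(discovery)))
  rows <- lapply(seq_len(nrow(validated)), function(i) {
    hit <- discovery[discovery$lectin == validated$lectin[i] &
                       discovery$feature == validated$protein[i], ,
                     drop = FALSE]
    if (!nrow(hit))
      return(data.frame(lectin = validated$lectin[i],
                        protein = validated$protein[i],
                        comparison = NA_character_, detected = FALSE,
                        log2fc = NA_real_, p = NA_real_,
                        concordant = NA, stringsAsFactors = FALSE))
    data.frame(lectin = validated$lectin[i],
               protein = validated$protein[i],
               comparison = hit$comparison, detected = TRUE,
               log2fc = hit$log2fc, p = hit$p,
               concordant = (hit$log2fc > 0) ==
                 (validated$direction[i] == "up"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
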