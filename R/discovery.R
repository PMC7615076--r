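#' Filter protein groups on evidence and decoy flags
#'
#' Removes contaminant-flagged and reverse-hit rows, rows with fewer than
#' \code{min_peptides} peptide identifications and rows with score below
#' \code{min_score}. Row order of survivors is preserved and the removal
#' reason of every dropped row is recorded.
#'
#' @param table a linear-scale DDA table (protein groups or peptides
#'   carrying the group-level \code{n_peptides} and \code{score}).
#' @param config an \code{\link{analysis_config}}.
#' @return the filtered table; attribute \code{removed} holds a
#'   data.frame of (id, reason) for dropped rows.
#' @export
filter_protein_groups <- function(table, config = analysis_config()) {
  if (identical(attr(table, "scale"), "log2"))
    stop("filtering expects a linear-scale table")
  reason <- rep(NA_character_, nrow(table))
  reason[table$score < config$min_score] <- "low_score"
  reason[table$n_peptides < config$min_peptides] <- "few_peptides"
  reason[table$reverse] <- "reverse"
  reason[table$contaminant] <- "contaminant"
  keep <- is.na(reason)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("lectin", "cohort", "scale", "samples", "standards"))
    attr(out, a) <- attr(table, a)
  attr(out, "removed") <- data.frame(id = table$id[!keep],
                                     reason = reason[!keep],
                                     stringsAsFactors = FALSE)
  out
}

#' Sum peptide intensities to protein-level quantities
#'
#' Protein quantity per sample is the sum of the observed intensities of
#' its mapped peptides; the protein is missing in a sample only when all
#' of its peptides are missing there.
#'
#' @param peptides a linear-scale peptide table with a \code{protein}
#'   column.
#' @return a protein-group table (one row per protein).
#' @export
sum_peptides_to_protein <- function(peptides) {
  if (!"protein" %in% names(peptides))
    stop("peptide table lacks a 'protein' mapping column")
  if (any(is.na(peptides$protein) | peptides$protein == ""))
    stop("peptide mapped to no protein")
  samples <- attr(peptides, "samples") %||%
    setdiff(names(peptides), c("id", "protein", "n_peptides", "score",
                               "contaminant", "reverse"))
  prot <- unique(peptides$protein)
  m <- as.matrix(peptides[samples])
  idx <- match(peptides$protein, prot)
  sums <- rowsum(ifelse(is.na(m), 0, m), idx)
  nobs <- rowsum((!is.na(m)) * 1L, idx)
  sums[nobs == 0L] <- NA_real_
  first <- match(prot, peptides$protein)
  out <- data.frame(id = prot,
                    n_peptides = peptides$n_peptides[first],
                    score = peptides$score[first],
                    contaminant = peptides$contaminant[first],
                    reverse = peptides$reverse[first],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(sums, optional = TRUE))
  names(out)[-(1:5)] <- samples
  rownames(out) <- NULL
  for (a in c("lectin", "cohort", "standards"))
    attr(out, a) <- attr(peptides, a)
  attr(out, "scale") <- "linear"
  attr(out, "samples") <- samples
  out
}

#' Log2-transform a linear-scale table
#'
#' @param table a DDA table on the linear scale.
#' @return the table with intensities log2-transformed and the scale flag
#'   updated.
#' @export
log2_transform <- function(table) {
  if (identical(attr(table, "scale"), "log2")) return(table)
  samples <- attr(table, "samples")
  for (s in samples) table[[s]] <- log2(table[[s]])
  attr(table, "scale") <- "log2"
  table
}

#' Local least squares imputation of one feature row
#'
#' Imputes the missing entries of \code{target} from the \code{k}
#' candidate rows most correlated (absolute Pearson, over the target's
#' observed samples) with it, by regressing the target on those
#' neighbours (with intercept) over the observed samples and predicting
#' the missing ones. With fewer than \code{k} eligible neighbours the
#' largest available number is used; a constant target is imputed with
#' its own constant.
#'
#' @param neighbours numeric matrix of candidate rows (features x
#'   samples), fully observed on the target's columns.
#' @param target numeric vector with \code{NA} at the entries to impute.
#' @param k neighbour count.
#' @return \code{target} with missing entries filled; attribute
#'   \code{neighbours} names the rows used.
#' @export
lls_impute_row <- function(neighbours, target, k) {
  obs <- which(!is.na(target))
  mis <- which(is.na(target))
  if (!length(mis)) return(target)
  if (length(obs) < 2L) stop("target needs >= 2 observed entries")
  ok <- stats::complete.cases(neighbours)
  neighbours <- neighbours[ok, , drop = FALSE]
  if (!nrow(neighbours)) stop("no eligible neighbour rows")
  if (stats::sd(target[obs]) == 0) {
    target[mis] <- target[obs][1L]
    attr(target, "neighbours") <- character()
    return(target)
  }
  r <- apply(neighbours[, obs, drop = FALSE], 1L, function(v) {
    if (stats::sd(v) == 0) 0 else stats::cor(v, target[obs])
  })
  use <- order(abs(r), decreasing = TRUE)[seq_len(min(k, nrow(neighbours)))]
  N <- neighbours[use, , drop = FALSE]
  X <- cbind(1, t(N[, obs, drop = FALSE]))
  beta <- pinv(X) %*% target[obs]
  target[mis] <- as.numeric(cbind(1, t(N[, mis, drop = FALSE])) %*% beta)
  attr(target, "neighbours") <- rownames(N) %||% as.character(use)
  target
}

#' Minimum-value imputation of one feature row
#'
#' Fills missing entries with draws from a normal distribution centred at
#' the per-sample minimum of the observed log2 values, with the supplied
#' SD — the left-censoring model for features absent from most samples.
#'
#' @param row numeric vector (log2) with \code{NA} at entries to impute.
#' @param sample_minima per-sample minima of the observed log2 matrix,
#'   aligned with \code{row}.
#' @param sd_estimate positive draw SD.
#' @param seed integer seed for the draws.
#' @return \code{row} with missing entries filled.
#' @export
min_value_impute_row <- function(row, sample_minima, sd_estimate, seed) {
  stopifnot(length(sample_minima) == length(row), sd_estimate >= 0)
  mis <- which(is.na(row))
  if (!length(mis)) return(row)
  if (anyNA(sample_minima[mis]))
    stop("no observed minimum for sample(s): ",
         paste(mis[is.na(sample_minima[mis])], collapse = ", "))
  row[mis] <- with_seed(seed,
    stats::rnorm(length(mis), sample_minima[mis], sd_estimate))
  row
}

#' Impute a log2 intensity table, routed by missingness fraction
#'
#' Features missing in fewer than \code{missing_frac_boundary} of samples
#' are treated as missing at random and imputed by local least squares on
#' their most correlated fully observed neighbours; features at or above
#' the boundary are treated as left-censored and imputed by
#' minimum-value normal draws. Observed entries are never altered; the
#' route taken for every row is recorded.
#'
#' @param table a log2-scale DDA table (see \code{\link{log2_transform}}).
#' @param config an \code{\link{analysis_config}}; uses
#'   \code{missing_frac_boundary}, \code{lls_k}, \code{minvalue_sd} and
#'   \code{seed}.
#' @return the table with no missing entries; attribute \code{routes} is
#'   a data.frame (id, route).
#' @export
impute_matrix <- function(table, config = analysis_config()) {
  if (!identical(attr(table, "scale"), "log2"))
    stop("imputation operates on the log2 scale")
  samples <- attr(table, "samples")
  m <- as.matrix(table[samples])
  rownames(m) <- table$id
  frac <- rowMeans(is.na(m))
  if (!any(frac == 0))
    stop("imputation requires at least one fully observed row")
  sd_est <- config$minvalue_sd %||% pooled_row_sd(m)
  minima <- apply(m, 2L, function(v) suppressWarnings(min(v, na.rm = TRUE)))
  minima[!is.finite(minima)] <- NA_real_
  complete <- m[frac == 0, , drop = FALSE]
  route <- ifelse(frac == 0, "none",
                  ifelse(frac < config$missing_frac_boundary, "lls",
                         "minvalue"))
  for (i in which(route == "lls")) {
    pool <- complete[setdiff(rownames(complete), rownames(m)[i]), ,
                     drop = FALSE]
    if (!nrow(pool) || sum(!is.na(m[i, ])) < 2L) {
      route[i] <- "minvalue_fallback"
      next
    }
    m[i, ] <- lls_impute_row(pool, m[i, ], config$lls_k)
  }
  for (i in which(route %in% c("minvalue", "minvalue_fallback"))) {
    m[i, ] <- min_value_impute_row(m[i, ], minima, sd_est,
                                   stream_seed(config$seed,
                                               paste0("minvalue-",
                                                      rownames(m)[i])))
  }
  table[samples] <- as.data.frame(m, optional = TRUE)
  attr(table, "routes") <- data.frame(id = rownames(m), route = route,
                                      stringsAsFactors = FALSE)
  attr(table, "minvalue_sd") <- sd_est
  table
}

# pooled SD over fully observed rows: sqrt of the mean within-row variance
pooled_row_sd <- function(m) {
  full <- m[rowSums(is.na(m)) == 0L, , drop = FALSE]
  if (!nrow(full)) stop("no fully observed rows to estimate the SD from")
  sqrt(mean(apply(full, 1L, stats::var)))
}

#' Two-group differential test on a log2 matrix
#'
#' Compares cases against one control group per feature. The default
#' variant is the pooled-variance two-sided Student t test; the moderated
#' variant shrinks the per-feature variances with an empirical-Bayes
#' moderated t (limma). The log2 fold change is mean(case) minus
#' mean(control); q values are left absent at this stage — shortlisting
#' is on unadjusted p.
#'
#' @param m log2 matrix, features x samples (column names = sample ids).
#' @param groups character vector of group labels aligned with columns.
#' @param comparison \code{"case-vs-benign"} or \code{"case-vs-healthy"}.
#' @param variant \code{"student"} or \code{"moderated"}.
#' @return data.frame (feature, comparison, log2fc, p, q, direction).
#' @export
differential_test <- function(m, groups,
                              comparison = c("case-vs-benign",
                                             "case-vs-healthy"),
                              variant = c("student", "moderated")) {
  comparison <- match.arg(comparison)
  variant <- match.arg(variant)
  ctrl <- if (comparison == "case-vs-benign") "benign" else "healthy"
  i1 <- which(groups == "case"); i0 <- which(groups == ctrl)
  if (length(i1) < 2L || length(i0) < 2L)
    stop("each group needs at least 2 samples")
  x1 <- m[, i1, drop = FALSE]; x0 <- m[, i0, drop = FALSE]
  lfc <- rowMeans(x1) - rowMeans(x0)
  if (variant == "student") {
    n1 <- length(i1); n0 <- length(i0)
    v1 <- apply(x1, 1L, stats::var); v0 <- apply(x0, 1L, stats::var)
    s2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(s2 * (1 / n1 + 1 / n0))
    tt <- ifelse(se == 0, ifelse(lfc == 0, 0, Inf * sign(lfc)), lfc / se)
    p <- 2 * stats::pt(-abs(tt), df = n1 + n0 - 2)
    p <- pmax(p, .Machine$double.xmin)  # keep p in (0, 1] for BH
  } else {
    sub <- cbind(x1, x0)
    design <- cbind(Intercept = 1,
                    case = rep(c(1, 0), c(length(i1), length(i0))))
    fit <- limma::eBayes(limma::lmFit(sub, design))
    p <- fit$p.value[, "case"]
    lfc <- fit$coefficients[, "case"]
  }
  data.frame(feature = rownames(m), comparison = comparison,
             log2fc = unname(lfc), p = unname(pmin(p, 1)),
             q = NA_real_,
             direction = ifelse(lfc > 0, "up",
                                ifelse(lfc < 0, "down", "flat")),
             stringsAsFactors = FALSE)
}

#' Shortlist differential candidates
#'
#' Strict mode keeps features with p below \code{p_discovery} and
#' absolute log2 fold change above \code{fc_discovery_log2}; expanded
#' mode keeps p below \code{p_expanded} with no fold-change condition
#' (used when assembling a larger target list for downstream assays).
#'
#' @param results a \code{\link{differential_test}} data.frame (extra
#'   columns such as lectin/cohort are carried through).
#' @param mode \code{"strict"} or \code{"expanded"}.
#' @param config an \code{\link{analysis_config}}.
#' @return the qualifying rows; attribute \code{provenance} records the
#'   thresholds applied.
#' @export
shortlist_candidates <- function(results, mode = c("strict", "expanded"),
                                 config = analysis_config()) {
  mode <- match.arg(mode)
  keep <- if (mode == "strict")
    results$p < config$p_discovery &
      abs(results$log2fc) > config$fc_discovery_log2
  else results$p < config$p_expanded
  out <- results[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <-
    if (mode == "strict")
      list(mode = mode, p = config$p_discovery,
           fc_log2 = config$fc_discovery_log2)
    else list(mode = mode, p = config$p_expanded, fc_log2 = NA_real_)
  out
}

#' Cross-cohort concordant candidates
#'
#' Keeps features whose log2 fold change exceeds \code{fc_thresh} in
#' absolute value in both cohorts with matching sign.
#'
#' @param res_a,res_b differential results from two cohorts on the same
#'   feature namespace (matched on feature and, when present,
#'   comparison).
#' @param fc_thresh absolute log2FC threshold applied to both.
#' @return merged data.frame of concordant features with per-cohort
#'   log2fc columns.
#' @export
cross_cohort_overlap <- function(res_a, res_b, fc_thresh = 0.5) {
  by <- intersect(c("feature", "comparison"),
                  intersect(names(res_a), names(res_b)))
  m <- merge(res_a[c(by, "log2fc", "p")], res_b[c(by, "log2fc", "p")],
             by = by, suffixes = c("_a", "_b"))
  keep <- abs(m$log2fc_a) > fc_thresh & abs(m$log2fc_b) > fc_thresh &
    sign(m$log2fc_a) == sign(m$log2fc_b)
  out <- m[keep, , drop = FALSE]
  out <- out[do.call(order, out[by]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap-aware candidate summary
#'
#' Summarises candidate sets labelled by lectin, cohort and comparison
#' the way a discovery-phase candidate table is reported: each cell lists
#' the proteins for one (cohort, comparison); the per-lectin total is the
#' number of distinct proteins in the union of that lectin's cells
#' (overlapping candidates counted once), and likewise for per-column
#' totals.
#'
#' @param candidates data.frame with columns lectin, cohort, comparison,
#'   protein.
#' @return list with \code{cells} (one row per lectin x cohort x
#'   comparison with comma-separated proteins and cell size),
#'   \code{lectin_totals} (named integer vector of distinct proteins per
#'   lectin) and \code{column_totals} (distinct proteins per cohort x
#'   comparison).
#' @export
summarize_candidates <- function(candidates) {
  stopifnot(all(c("lectin", "cohort", "comparison", "protein") %in%
                  names(candidates)))
  candidates <- unique(candidates[c("lectin", "cohort", "comparison",
                                    "protein")])
  cells <- stats::aggregate(protein ~ lectin + cohort + comparison,
                            candidates,
                            function(p) paste(sort(unique(p)),
                                              collapse = ","))
  sizes <- stats::aggregate(protein ~ lectin + cohort + comparison,
                            candidates, function(p) length(unique(p)))
  cells$n <- sizes$protein
  cells <- cells[order(cells$lectin, cells$comparison, cells$cohort), ]
  rownames(cells) <- NULL
  lect <- sort(unique(candidates$lectin))
  lectin_totals <- vapply(lect, function(l)
    length(unique(candidates$protein[candidates$lectin == l])), 1L)
  cols <- unique(candidates[c("cohort", "comparison")])
  cols <- cols[order(cols$comparison, cols$cohort), , drop = FALSE]
  cols$n_distinct <- mapply(function(ch, cm)
    length(unique(candidates$protein[candidates$cohort == ch &
                                       candidates$comparison == cm])),
    cols$cohort, cols$comparison)
  rownames(cols) <- NULL
  list(cells = cells, lectin_totals = lectin_totals, column_totals = cols)
}

#' Rank lectins by candidate yield
#'
#' Orders lectins by either the distinct-protein union count or the count
#' of proteins discovered in both cohorts, breaking ties
#' lexicographically.
#'
#' @param candidates the candidate data.frame given to
#'   \code{\link{summarize_candidates}}.
#' @param n how many lectins to return.
#' @param metric \code{"union"} (distinct proteins over all cells) or
#'   \code{"both_cohort"} (distinct proteins appearing in both cohorts).
#' @return character vector of lectins, best first; attribute
#'   \code{counts} carries the metric values.
#' @export
rank_lectins <- function(candidates, n,
                         metric = c("union", "both_cohort")) {
  metric <- match.arg(metric)
  lect <- sort(unique(candidates$lectin))
  counts <- if (metric == "union")
    summarize_candidates(candidates)$lectin_totals
  else vapply(lect, function(l) {
    sub <- candidates[candidates$lectin == l, ]
    per_cohort <- split(sub$protein, sub$cohort)
    if (length(per_cohort) < 2L) return(0L)
    length(Reduce(intersect, lapply(per_cohort, unique)))
  }, 1L)
  counts <- counts[lect]
  ord <- order(-counts, lect)
  if (n > length(lect)) {
    warning("requested more lectins than available; returning all")
    n <- length(lect)
  }
  ties <- any(duplicated(counts[ord][seq_len(n)])) ||
    (n < length(lect) && counts[ord][n] == counts[ord][n + 1L])
  if (ties) message("lectin ranking contains ties; broken lexicographically")
  out <- lect[ord][seq_len(n)]
  attr(out, "counts") <- counts[ord]
  out
}
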