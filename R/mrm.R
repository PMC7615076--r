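#' Aggregate MRM transitions to a peptide matrix
#'
#' Peptide quantity per sample is the sum of its transition peak areas,
#' log2-transformed (sum first, then log). An entry is missing when no
#' transition was observed, or the summed area is zero.
#'
#' @param table a transition table (see
#'   \code{\link{read_transition_report}}).
#' @return numeric matrix peptides x samples of log2 summed areas, with
#'   attributes \code{protein_map} (named character: peptide -> protein),
#'   \code{standards} and \code{lectin}.
#' @export
aggregate_transitions <- function(table) {
  stopifnot(all(c("protein", "peptide", "transition", "sample", "area")
                %in% names(table)))
  peptides <- sort(unique(table$peptide))
  samples <- sort(unique(table$sample))
  sums <- matrix(0, length(peptides), length(samples),
                 dimnames = list(peptides, samples))
  seen <- matrix(FALSE, length(peptides), length(samples),
                 dimnames = list(peptides, samples))
  i <- cbind(match(table$peptide, peptides), match(table$sample, samples))
  obs <- !is.na(table$area)
  add <- table$area; add[!obs] <- 0
  for (r in seq_len(nrow(table))) {
    sums[i[r, 1], i[r, 2]] <- sums[i[r, 1], i[r, 2]] + add[r]
    if (obs[r]) seen[i[r, 1], i[r, 2]] <- TRUE
  }
  m <- log2(sums)
  m[!seen | sums == 0] <- NA_real_
  pm <- table$protein[match(peptides, table$peptide)]
  names(pm) <- peptides
  attr(m, "protein_map") <- pm
  attr(m, "standards") <- attr(table, "standards")
  attr(m, "lectin") <- attr(table, "lectin")
  attr(m, "scale") <- "log2"
  m
}

#' Percent coefficient of variation
#'
#' 100 x SD / mean, computed on linear-scale summed areas — the
#' run-quality statistic for internal-standard peptides.
#'
#' @param areas positive linear-scale values, length >= 2.
#' @return percent CV.
#' @export
compute_cv <- function(areas) {
  if (length(areas) < 2L) stop("need at least 2 values")
  m <- mean(areas)
  if (!is.finite(m) || m <= 0) stop("non-positive mean area")
  100 * stats::sd(areas) / m
}

#' Flag outlier samples from internal-standard levels
#'
#' Scores each sample by the robust z of its mean log2 standard-peptide
#' area against the batch median (scaled by 1.4826 x MAD); samples above
#' the threshold are flagged. Flags are advisory — removal is a separate
#' step the caller logs.
#'
#' @param m peptide matrix from \code{\link{aggregate_transitions}} (log2
#'   scale) containing the standard peptides.
#' @param standard_ids character vector of standard peptide row names;
#'   defaults to the matrix's registered standards.
#' @param robust_z_threshold flag threshold (default 3.5).
#' @return data.frame (sample, standard_level, score, flagged).
#' @export
flag_outlier_samples <- function(m, standard_ids = NULL,
                                 robust_z_threshold = 3.5) {
  standard_ids <- standard_ids %||%
    unlist(attr(m, "standards"), use.names = FALSE)
  if (!length(standard_ids)) stop("standard-peptide registry is empty")
  miss <- setdiff(standard_ids, rownames(m))
  if (length(miss))
    stop("standard peptide(s) absent from the matrix: ",
         paste(miss, collapse = ", "))
  lvl <- colMeans(m[standard_ids, , drop = FALSE], na.rm = TRUE)
  med <- stats::median(lvl)
  s <- stats::mad(lvl)  # 1.4826 * median absolute deviation
  dev <- abs(lvl - med)
  if (s == 0) {
    score <- ifelse(dev == 0, 0, Inf)
    if (any(dev > 0))
      warning("zero MAD with deviating samples; flagging all deviations")
  } else score <- dev / s
  data.frame(sample = colnames(m), standard_level = unname(lvl),
             score = unname(score),
             flagged = unname(score > robust_z_threshold),
             stringsAsFactors = FALSE)
}

#' Internal-standard QC report
#'
#' Computes the linear-scale percent CV of every registered standard
#' peptide (on summed transition areas, over retained samples), compares
#' each against the CV limit, and attaches robust-z outlier flags per
#' sample.
#'
#' @param table a transition table with a standards registry.
#' @param config an \code{\link{analysis_config}}.
#' @param retain optional character vector of samples to evaluate
#'   (default all).
#' @return list with \code{standards} (peptide, role, cv_pct, pass),
#'   \code{samples} (outlier flags) and \code{pass} (all standards within
#'   the limit).
#' @export
qc_report <- function(table, config = analysis_config(), retain = NULL) {
  reg <- attr(table, "standards")
  if (is.null(reg)) stop("transition table carries no standards registry")
  m <- aggregate_transitions(table)
  if (!is.null(retain)) m <- m[, retain, drop = FALSE]
  std <- data.frame(
    peptide = c(reg$ovalbumin, reg$sis),
    role = rep(c("ovalbumin", "sis"),
               c(length(reg$ovalbumin), length(reg$sis))),
    stringsAsFactors = FALSE)
  std$cv_pct <- vapply(std$peptide, function(p)
    compute_cv(2^m[p, !is.na(m[p, ])]), numeric(1))
  std$pass <- std$cv_pct < config$cv_limit_pct
  flags <- flag_outlier_samples(m, std$peptide, config$outlier_robust_z)
  list(standards = std, samples = flags, pass = all(std$pass))
}

#' Standardise peptides to the ovalbumin internal standards
#'
#' Subtracts, per sample, the mean log2 level of the ovalbumin standard
#' peptides from every peptide — removing sample-level loading shifts.
#' Standard peptides are dropped from the returned matrix so they cannot
#' enter downstream feature sets.
#'
#' @param m peptide matrix (log2).
#' @param standard_ids ovalbumin standard peptide ids; defaults to the
#'   registered ovalbumin set.
#' @return the standardised matrix without the standard rows.
#' @export
standardize_to_ovalbumin <- function(m, standard_ids = NULL) {
  standard_ids <- standard_ids %||% attr(m, "standards")$ovalbumin
  if (!length(standard_ids)) stop("no ovalbumin standards registered")
  miss <- setdiff(standard_ids, rownames(m))
  if (length(miss))
    stop("standard peptide(s) absent: ", paste(miss, collapse = ", "))
  ref <- m[standard_ids, , drop = FALSE]
  if (anyNA(ref))
    stop("missing standard entry in retained sample(s)")
  shift <- colMeans(ref)
  out <- m[setdiff(rownames(m), standard_ids), , drop = FALSE]
  out <- sweep(out, 2L, shift)
  for (a in c("protein_map", "standards", "lectin", "scale"))
    attr(out, a) <- attr(m, a)
  attr(out, "protein_map") <-
    attr(m, "protein_map")[rownames(out)]
  out
}
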