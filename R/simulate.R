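#' Simulation configuration for a synthetic lectin-pulldown cohort
#'
#' Defines a three-group (case / benign / healthy) serum glycoproteomics
#' cohort measured across several lectin pulldowns. Protein abundance is
#' log2-normal with a per-protein baseline drawn once per cohort; planted
#' group effects are registered per (lectin, protein, comparison);
#' missingness combines an intensity-dependent (left-censoring, MNAR)
#' component with a uniform (MCAR) component; internal-standard peptides
#' (ovalbumin-like plus spiked stable-isotope standards) are present in
#' every sample with a low target coefficient of variation.
#'
#' Default group sizes mirror the discovery design of ten cases, ten
#' benign and ten healthy age-matched samples; validation-scale cohorts
#' (39/28/28) are configured by overriding the counts.
#'
#' @param n_case,n_benign,n_healthy samples per group.
#' @param lectins character vector of lectin pulldowns.
#' @param n_proteins number of genuine (non-decoy) proteins per lectin.
#' @param peptides_per_protein integer range (length 2) of peptides mapped
#'   to each protein.
#' @param transitions_per_peptide integer range (length 2) of MRM
#'   transitions per peptide.
#' @param baseline_log2_mean,baseline_log2_sd population distribution of
#'   per-protein baseline log2 intensity.
#' @param sample_sd within-group biological plus technical SD on the log2
#'   scale.
#' @param effect_table data.frame with columns lectin, protein, comparison
#'   (one of \code{"case-vs-benign"}, \code{"case-vs-healthy"}), effect
#'   (planted log2 fold change, case minus control). May be \code{NULL}.
#' @param mnar_midpoint,mnar_slope logistic missingness-versus-intensity
#'   parameters: deletion probability
#'   \code{plogis((mnar_midpoint - log2 intensity) * mnar_slope)}.
#'   \code{mnar_slope = 0} disables intensity-dependent missingness.
#' @param mcar_rate additional uniform missingness fraction in [0, 1).
#' @param n_standard_peptides total internal-standard peptides (split
#'   evenly between ovalbumin-like and SIS-like).
#' @param standard_cv_target target linear-scale percent CV of the
#'   internal standards.
#' @param decoy_rates list with contaminant, reverse and low_evidence
#'   rates (fractions of \code{n_proteins}) of junk rows injected so the
#'   protein-group filter has work to do.
#' @param outlier_batch optional list(lectin, samples, shift_log2,
#'   inflation) describing an instrument-failure batch applied to the MRM
#'   tables (see \code{\link{inject_outlier_batch}}).
#' @param cohort cohort label carried into sample annotation.
#' @param seed root seed; all stage streams derive from it.
#' @return a list of class \code{glyco_simconfig}.
#' @export
simulation_config <- function(n_case = 10L, n_benign = 10L, n_healthy = 10L,
                              lectins = c("AAL", "CON-A", "ECA", "L-PHA",
                                          "SNA", "STL", "WFA"),
                              n_proteins = 100L,
                              peptides_per_protein = c(2L, 6L),
                              transitions_per_peptide = c(4L, 5L),
                              baseline_log2_mean = 20,
                              baseline_log2_sd = 2,
                              sample_sd = 1,
                              effect_table = NULL,
                              mnar_midpoint = 17,
                              mnar_slope = 1,
                              mcar_rate = 0.02,
                              n_standard_peptides = 6L,
                              standard_cv_target = 8,
                              decoy_rates = list(contaminant = 0.05,
                                                 reverse = 0.05,
                                                 low_evidence = 0.10),
                              outlier_batch = NULL,
                              cohort = "SIM",
                              seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_benign = as.integer(n_benign),
              n_healthy = as.integer(n_healthy), lectins = lectins,
              n_proteins = as.integer(n_proteins),
              peptides_per_protein = as.integer(peptides_per_protein),
              transitions_per_peptide = as.integer(transitions_per_peptide),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              sample_sd = sample_sd,
              effect_table = effect_table,
              mnar_midpoint = mnar_midpoint, mnar_slope = mnar_slope,
              mcar_rate = mcar_rate,
              n_standard_peptides = as.integer(n_standard_peptides),
              standard_cv_target = standard_cv_target,
              decoy_rates = decoy_rates,
              outlier_batch = outlier_batch,
              cohort = cohort, seed = as.integer(seed))
  if (any(c(cfg$n_case, cfg$n_benign, cfg$n_healthy, cfg$n_proteins) <= 0L))
    stop("group sizes and n_proteins must be positive")
  if (cfg$mcar_rate < 0 || cfg$mcar_rate >= 1)
    stop("'mcar_rate' must lie in [0, 1)")
  if (cfg$standard_cv_target <= 0) stop("'standard_cv_target' must be > 0")
  if (length(cfg$peptides_per_protein) != 2L ||
      any(cfg$peptides_per_protein < 1L))
    stop("'peptides_per_protein' must be a positive integer range")
  if (!is.null(cfg$effect_table)) {
    et <- cfg$effect_table
    need <- c("lectin", "protein", "comparison", "effect")
    if (!all(need %in% names(et)))
      stop("effect_table needs columns: ", paste(need, collapse = ", "))
    if (!all(et$comparison %in% c("case-vs-benign", "case-vs-healthy")))
      stop("effect_table comparisons must be case-vs-benign/case-vs-healthy")
    if (!all(et$lectin %in% cfg$lectins))
      stop("effect_table references lectins absent from the configuration")
    prot_names <- protein_names(cfg$n_proteins)
    if (!all(et$protein %in% prot_names))
      stop("effect_table references proteins absent from the configuration")
  }
  class(cfg) <- "glyco_simconfig"
  cfg
}

protein_names <- function(n) sprintf("PROT%03d", seq_len(n))

# Published ovalbumin tryptic peptides and the spiked stable-isotope
# standards used for retention-time monitoring; reused here as realistic
# internal-standard identifiers.
OVALBUMIN_PEPTIDES <- c("GGLEPINFQTAADQAR", "ISQAVHAAHAEINEAGR",
                        "YPILPEYLQCVK")
SIS_PEPTIDES <- c("VTSIQDWVQK", "NLAVSQVVHK", "LSPIYNLVPVK")

# sample() treats a scalar as 1:n; degenerate ranges must stay fixed
sample_range <- function(range, n) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

standard_registry <- function(n_standard) {
  n_ova <- ceiling(n_standard / 2)
  n_sis <- n_standard - n_ova
  ova <- rep_len(OVALBUMIN_PEPTIDES, n_ova)
  sis <- rep_len(SIS_PEPTIDES, max(n_sis, 0L))
  if (n_ova > 3L) ova <- paste0(ova, "_", seq_len(n_ova))
  if (n_sis > 3L) sis <- paste0(sis, "_", seq_len(n_sis))
  list(ovalbumin = ova, sis = sis)
}

#' Simulate a three-group multi-lectin cohort with known ground truth
#'
#' Generates, for each configured lectin, a peptide-level DDA intensity
#' table (linear scale, with contaminant / reverse / low-evidence decoy
#' rows and MNAR+MCAR missingness) and a long-format MRM transition
#' table, together with sample annotation and a truth registry of the
#' planted effects and deleted entries. Identical configuration and seed
#' reproduce identical output.
#'
#' A planted log2 effect for comparison case-vs-X is realised by shifting
#' group X down by the effect size, so that the case-minus-X contrast
#' equals the planted value while the other comparison is untouched.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with elements \code{metadata} (sample annotation
#'   data.frame), \code{dda} (named list of peptide-level tables, one per
#'   lectin), \code{mrm} (named list of transition tables), and
#'   \code{truth} (planted-effect registry and missingness record).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "glyco_simconfig"))
  groups <- c(rep("case", config$n_case), rep("benign", config$n_benign),
              rep("healthy", config$n_healthy))
  n <- length(groups)
  meta <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    group = groups,
    cohort = config$cohort,
    batch = "B1",
    age = with_seed(stream_seed(config$seed, "age"),
                    round(stats::rnorm(n, 60, 8), 1)),
    stringsAsFactors = FALSE)

  dda <- list(); mrm <- list()
  missing_record <- list()
  for (lectin in config$lectins) {
    sim <- simulate_lectin(config, meta, lectin)
    dda[[lectin]] <- sim$dda
    mrm[[lectin]] <- sim$mrm
    missing_record[[lectin]] <- sim$missing
  }

  truth <- list(
    planted_effects = config$effect_table %||%
      data.frame(lectin = character(), protein = character(),
                 comparison = character(), effect = numeric(),
                 stringsAsFactors = FALSE),
    missing_record = missing_record)

  out <- list(metadata = meta, dda = dda, mrm = mrm, truth = truth)
  if (!is.null(config$outlier_batch)) {
    ob <- config$outlier_batch
    out$mrm <- inject_outlier_batch(out$mrm, ob)
    out$truth$outlier_batch <- ob
  }
  out
}

simulate_lectin <- function(config, meta, lectin) {
  n <- nrow(meta)
  prot <- protein_names(config$n_proteins)
  with_seed(stream_seed(config$seed, paste0("dda-", lectin)), {
    n_pep <- sample_range(config$peptides_per_protein, config$n_proteins)
    baseline <- stats::rnorm(config$n_proteins, config$baseline_log2_mean,
                             config$baseline_log2_sd)
    pep_protein <- rep(prot, n_pep)
    pep_id <- unlist(lapply(seq_along(prot), function(i)
      sprintf("%s_pep%d", prot[i], seq_len(n_pep[i]))))
    pep_offset <- stats::rnorm(length(pep_id), -1, 0.5)
    score <- round(stats::runif(config$n_proteins, 10, 320), 2)

    # group-level shift per protein: planted effect moves the named
    # control group by -effect so case-minus-control equals the effect
    shift <- matrix(0, config$n_proteins, n,
                    dimnames = list(prot, meta$sample_id))
    et <- config$effect_table
    if (!is.null(et)) {
      et <- et[et$lectin == lectin, , drop = FALSE]
      for (i in seq_len(nrow(et))) {
        ctrl <- if (et$comparison[i] == "case-vs-benign") "benign"
                else "healthy"
        shift[et$protein[i], meta$group == ctrl] <-
          shift[et$protein[i], meta$group == ctrl] - et$effect[i]
      }
    }

    mu <- baseline[match(pep_protein, prot)] + pep_offset
    y <- matrix(stats::rnorm(length(pep_id) * n, sd = config$sample_sd),
                length(pep_id), n) + mu +
      shift[match(pep_protein, prot), , drop = FALSE]
    dimnames(y) <- list(pep_id, meta$sample_id)

    # missingness: intensity-dependent left censoring, then uniform MCAR
    del_mnar <- matrix(FALSE, nrow(y), n)
    if (config$mnar_slope > 0) {
      p_del <- stats::plogis((config$mnar_midpoint - y) * config$mnar_slope)
      del_mnar <- matrix(stats::runif(length(y)) < p_del, nrow(y), n)
    }
    del_mcar <- matrix(stats::runif(length(y)) < config$mcar_rate,
                       nrow(y), n) & !del_mnar
    intensity <- 2^y
    intensity[del_mnar | del_mcar] <- NA_real_

    missing <- data.frame(
      feature = rownames(y)[row(y)[del_mnar | del_mcar]],
      sample = colnames(y)[col(y)[del_mnar | del_mcar]],
      mechanism = ifelse(del_mnar[del_mnar | del_mcar], "mnar", "mcar"),
      stringsAsFactors = FALSE)

    # internal standards: group-independent, low linear-scale CV,
    # never subject to missingness
    reg <- standard_registry(config$n_standard_peptides)
    std_pep <- c(reg$ovalbumin, reg$sis)
    std_protein <- rep(c("OVAL", "SIS"),
                       c(length(reg$ovalbumin), length(reg$sis)))
    sdlog <- sqrt(log(1 + (config$standard_cv_target / 100)^2))
    std_base <- 2^stats::rnorm(length(std_pep), config$baseline_log2_mean + 2,
                               0.5)
    std_area <- matrix(stats::rlnorm(length(std_pep) * n,
                                     meanlog = rep(log(std_base), n),
                                     sdlog = sdlog),
                       length(std_pep), n,
                       dimnames = list(std_pep, meta$sample_id))

    # decoy rows exercising the protein-group filter
    dr <- config$decoy_rates
    n_cont <- round(dr$contaminant * config$n_proteins)
    n_rev <- round(dr$reverse * config$n_proteins)
    n_low <- round(dr$low_evidence * config$n_proteins)
    n_dec <- n_cont + n_rev + n_low
    dec_protein <- c(sprintf("CON__KRT%02d", seq_len(n_cont)),
                     sprintf("REV__PROT%03d", seq_len(n_rev)),
                     sprintf("LOWEV%03d", seq_len(n_low)))
    dec_flag_cont <- rep(c(TRUE, FALSE, FALSE), c(n_cont, n_rev, n_low))
    dec_flag_rev <- rep(c(FALSE, TRUE, FALSE), c(n_cont, n_rev, n_low))
    # low-evidence decoys fail on peptide count or score
    dec_npep <- rep(2L, n_dec)
    dec_score <- round(stats::runif(n_dec, 10, 100), 2)
    if (n_low > 0L) {
      one_pep <- stats::runif(n_low) < 0.5
      dec_npep[n_cont + n_rev + which(one_pep)] <- 1L
      dec_score[n_cont + n_rev + which(!one_pep)] <-
        round(stats::runif(sum(!one_pep), 0.1, 4.9), 2)
    }
    dec_area <- 2^matrix(stats::rnorm(n_dec * n, config$baseline_log2_mean,
                                      config$baseline_log2_sd),
                         n_dec, n, dimnames = list(dec_protein,
                                                   meta$sample_id))

    dda <- data.frame(
      id = c(pep_id, std_pep, dec_protein),
      protein = c(pep_protein, std_protein, dec_protein),
      n_peptides = c(n_pep[match(pep_protein, prot)],
                     rep(3L, length(std_pep)), dec_npep),
      score = c(score[match(pep_protein, prot)],
                rep(300, length(std_pep)), dec_score),
      contaminant = c(rep(FALSE, length(pep_id) + length(std_pep)),
                      dec_flag_cont),
      reverse = c(rep(FALSE, length(pep_id) + length(std_pep)),
                  dec_flag_rev),
      stringsAsFactors = FALSE)
    dda <- cbind(dda, as.data.frame(rbind(intensity, std_area, dec_area),
                                    optional = TRUE))
    rownames(dda) <- NULL
    attr(dda, "lectin") <- lectin
    attr(dda, "cohort") <- config$cohort
    attr(dda, "scale") <- "linear"
    attr(dda, "samples") <- meta$sample_id
    attr(dda, "standards") <- reg
    attr(dda, "missing_record") <- missing
    dda
  }) -> dda_out

  mrm_out <- with_seed(stream_seed(config$seed, paste0("mrm-", lectin)), {
    # targeted assay: complete measurements, transition areas split each
    # peptide's abundance by fixed weights plus small multiplicative noise
    samples <- attr(dda_out, "samples")
    keep <- !(dda_out$contaminant | dda_out$reverse |
                grepl("^LOWEV", dda_out$id))
    pep <- dda_out[keep, , drop = FALSE]
    n_tr <- sample_range(config$transitions_per_peptide, nrow(pep))
    rows <- vector("list", nrow(pep))
    # regenerate complete (pre-deletion) abundances for targeted assay
    for (i in seq_len(nrow(pep))) {
      area_pep <- as.numeric(pep[i, samples])
      if (anyNA(area_pep)) {
        obs <- stats::median(log2(area_pep), na.rm = TRUE)
        # fully censored in DDA: targeted assay still measures it, near
        # the censoring midpoint
        if (!is.finite(obs)) obs <- config$mnar_midpoint
        area_pep[is.na(area_pep)] <-
          2^stats::rnorm(sum(is.na(area_pep)), obs, config$sample_sd)
      }
      w <- stats::runif(n_tr[i], 0.5, 1.5)
      w <- w / sum(w)
      noise <- matrix(exp(stats::rnorm(n_tr[i] * length(samples), 0, 0.05)),
                      n_tr[i], length(samples))
      areas <- outer(w, area_pep) * noise
      rows[[i]] <- data.frame(
        protein = pep$protein[i], peptide = pep$id[i],
        transition = sprintf("%s_tr%d", pep$id[i], seq_len(n_tr[i])),
        sample = rep(samples, each = n_tr[i]),
        area = as.numeric(areas), stringsAsFactors = FALSE)
    }
    tt <- do.call(rbind, rows)
    attr(tt, "lectin") <- lectin
    attr(tt, "cohort") <- config$cohort
    attr(tt, "standards") <- attr(dda_out, "standards")
    tt
  })

  list(dda = dda_out, mrm = mrm_out,
       missing = attr(dda_out, "missing_record"))
}

#' Perturb an instrument-failure batch of MRM samples
#'
#' Emulates a re-run / low-volume aberration: every transition area of
#' the named samples in one lectin's table is shifted on the log2 scale
#' and its spread about the per-peptide mean inflated. A shift of 0 with
#' inflation 1 is the identity.
#'
#' @param tables named list of transition tables (or a single table).
#' @param spec list with elements \code{lectin}, \code{samples},
#'   \code{shift_log2} (location shift, log2 units) and \code{inflation}
#'   (variance inflation factor, deviations multiplied by its square
#'   root).
#' @return the tables with the flagged samples perturbed.
#' @export
inject_outlier_batch <- function(tables, spec) {
  single <- is.data.frame(tables)
  if (single) tables <- stats::setNames(list(tables),
                                        attr(tables, "lectin") %||% "L1")
  stopifnot(all(c("lectin", "samples") %in% names(spec)))
  shift <- spec$shift_log2 %||% 0
  infl <- spec$inflation %||% 1
  if (infl <= 0) stop("'inflation' must be > 0")
  if (!spec$lectin %in% names(tables))
    stop("unknown lectin: ", spec$lectin)
  tt <- tables[[spec$lectin]]
  unknown <- setdiff(spec$samples, unique(tt$sample))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  flagged <- tt$sample %in% spec$samples
  l2 <- log2(tt$area)
  pep_mean <- stats::ave(l2, tt$peptide, FUN = mean)
  l2[flagged] <- pep_mean[flagged] +
    sqrt(infl) * (l2[flagged] - pep_mean[flagged]) + shift
  tt$area <- 2^l2
  tables[[spec$lectin]] <- tt
  if (single) tables[[1L]] else tables
}
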