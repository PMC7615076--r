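small_config <- function(mcar_rate = 0.05, ...) {
  simulation_config(lectins = "AAL", n_proteins = 30L,
                    peptides_per_protein = c(2L, 2L),
                    mnar_slope = 0, mcar_rate = mcar_rate,
                    decoy_rates = list(contaminant = 0, reverse = 0,
                                       low_evidence = 0),
                    seed = 42L, ...)
}

test_that("identical configuration and seed reproduce identical tables", {
  a <- simulate_cohort(small_config())
  b <- simulate_cohort(small_config())
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$dda, b$dda)
  expect_identical(a$mrm, b$mrm)
  expect_identical(a$truth, b$truth)
})

test_that("MCAR deletion matches its nominal rate", {
  cfg <- simulation_config(lectins = "AAL", n_proteins = 100L,
                           peptides_per_protein = c(1L, 1L),
                           mnar_slope = 0, mcar_rate = 0.1,
                           decoy_rates = list(contaminant = 0, reverse = 0,
                                              low_evidence = 0),
                           seed = 3L)
  sim <- simulate_cohort(cfg)
  d <- sim$dda$AAL
  feat <- d[!d$protein %in% c("OVAL", "SIS"), attr(d, "samples")]
  n_cells <- prod(dim(feat))
  realized <- sum(is.na(feat)) / n_cells
  se <- sqrt(0.1 * 0.9 / n_cells)
  expect_lt(abs(realized - 0.1), 3 * se)
  rec <- sim$truth$missing_record$AAL
  expect_equal(nrow(rec), sum(is.na(feat)))
  expect_true(all(rec$mechanism == "mcar"))
})

test_that("planted effects shift the targeted comparison only", {
  et <- data.frame(lectin = "AAL", protein = sprintf("PROT%03d", 1:10),
                   comparison = "case-vs-benign", effect = 2)
  cfg <- small_config(n_case = 30L, n_benign = 30L, n_healthy = 30L,
                      effect_table = et, mcar_rate = 0)
  sim <- simulate_cohort(cfg)
  res <- discover_dda(sim$dda$AAL, sim$metadata)
  hit <- res[res$feature %in% et$protein, ]
  lfc_b <- hit$log2fc[hit$comparison == "case-vs-benign"]
  lfc_h <- hit$log2fc[hit$comparison == "case-vs-healthy"]
  expect_lt(abs(mean(lfc_b) - 2), 0.25)
  expect_lt(abs(mean(lfc_h)), 0.25)
})

test_that("intensity-dependent deletion removes low entries preferentially", {
  base <- list(lectins = "AAL", n_proteins = 80L,
               peptides_per_protein = c(1L, 1L), mcar_rate = 0,
               decoy_rates = list(contaminant = 0, reverse = 0,
                                  low_evidence = 0),
               baseline_log2_sd = 3, seed = 8L)
  on <- do.call(simulation_config, c(base, mnar_midpoint = 18,
                                     mnar_slope = 1.5))
  off <- do.call(simulation_config, c(base, mnar_slope = 0))
  # value draws precede deletion draws in the stream, so the underlying
  # intensities coincide and 'off' reveals the pre-deletion values
  sim_on <- simulate_cohort(on)$dda$AAL
  sim_off <- simulate_cohort(off)$dda$AAL
  samples <- attr(sim_on, "samples")
  keep <- !sim_on$protein %in% c("OVAL", "SIS")
  m_on <- log2(as.matrix(sim_on[keep, samples]))
  m_full <- log2(as.matrix(sim_off[keep, samples]))
  expect_false(anyNA(m_full))
  has_miss <- rowSums(is.na(m_on)) > 0
  expect_true(any(has_miss))
  expect_gt(mean(m_on[has_miss, ], na.rm = TRUE),
            mean(m_full[has_miss, ]))
})

test_that("decoy rows are injected at the configured rates and filtered", {
  cfg <- simulation_config(lectins = "AAL", n_proteins = 100L,
                           peptides_per_protein = c(2L, 2L),
                           mnar_slope = 0, mcar_rate = 0, seed = 2L)
  d <- simulate_cohort(cfg)$dda$AAL
  expect_equal(sum(d$contaminant), 5L)
  expect_equal(sum(d$reverse), 5L)
  expect_equal(sum(d$n_peptides < 2 | d$score < 5), 10L)
  filt <- filter_protein_groups(d)
  expect_false(any(filt$contaminant | filt$reverse |
                     filt$n_peptides < 2 | filt$score < 5))
  expect_equal(sort(unique(attr(filt, "removed")$reason)),
               c("contaminant", "few_peptides", "low_score", "reverse"))
})

test_that("outlier batch injection is the identity at null settings", {
  sim <- simulate_cohort(small_config())
  tt <- sim$mrm$AAL
  same <- inject_outlier_batch(list(AAL = tt),
                               list(lectin = "AAL",
                                    samples = c("S001", "S002"),
                                    shift_log2 = 0, inflation = 1))$AAL
  expect_equal(same$area, tt$area, tolerance = 1e-12)
  expect_error(
    inject_outlier_batch(list(AAL = tt),
                         list(lectin = "AAL", samples = "NOPE",
                              shift_log2 = -1, inflation = 2)),
    "unknown sample")
  shifted <- inject_outlier_batch(list(AAL = tt),
                                  list(lectin = "AAL", samples = "S001",
                                       shift_log2 = -1,
                                       inflation = 1))$AAL
  idx <- shifted$sample == "S001"
  expect_equal(log2(shifted$area[idx]), log2(tt$area[idx]) - 1)
  expect_equal(shifted$area[!idx], tt$area[!idx])
})
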